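# LED-array construction, illumination wavevectors, parallel scheduling

test_that("LED counts: closed form matches brute-force enumeration for all layouts", {
  # brute-force oracle: enumerate per-well segment lattice points, deduplicate
  brute <- function(layout, pitch = 3, seg = 18) {
    pts <- unique(do.call(rbind, lapply(seq_len(nrow(layout$centers)), function(w) {
      cw <- layout$centers[w, ]
      expand.grid(x = cw$x_mm + seq(-seg / 2, seg / 2, pitch),
                  y = cw$y_mm + seq(-seg / 2, seg / 2, pitch))
    })))
    nrow(unique(round(pts * 1e6)))
  }
  for (nr in c(1, 2, 3, 8)) for (nc in c(1, 2, 5, 12)) {
    layout <- well_layout(n_rows = nr, n_cols = nc)
    grid <- build_led_grid(layout)
    expect_identical(nrow(grid$positions), led_count_closed_form(layout))
    expect_identical(nrow(grid$positions), brute(layout))
  }
  # the instrument numbers: 96 wells -> 40 x 28 = 1120; 1 well -> 7^2 = 49
  expect_identical(nrow(build_led_grid(well_layout())$positions), 1120L)
  expect_identical(nrow(build_led_grid(well_layout(1, 1))$positions), 49L)
  expect_identical(nrow(build_led_grid(well_layout(2, 2))$positions), 100L)
})

test_that("LED grid invariants: unique lattice positions, commensurate pitches", {
  g <- build_led_grid(well_layout())
  expect_false(any(duplicated(g$positions[c("ix", "iy")])))
  # every coordinate is an integer multiple of the pitch from the grid origin
  rel <- (g$positions$x_mm - g$origin_mm[1]) / g$led_pitch_mm
  expect_true(all(abs(rel - round(rel)) < 1e-9))
  expect_error(build_led_grid(well_layout(), led_pitch_mm = 2.5),
               "must divide")
  expect_error(build_led_grid(well_layout(), segment_width_mm = 6), ">=")
})

test_that("segment reuse fraction matches geometry and a rasterized overlap oracle", {
  expect_equal(segment_reuse_fraction(9, 18), 0.75)
  expect_equal(segment_reuse_fraction(9, 9), 0)
  expect_equal(segment_reuse_fraction(6, 18), 8 / 9)
  # rasterized oracle: the reuse fraction is the amortized-area statement
  # 1 - union(n wells) / (n^2 seg^2) as the lattice grows. Rasterize the
  # union for a small lattice to validate the closed-form union area, then
  # extrapolate with it.
  raster_union <- function(pitch, seg, n, res = 0.25) {
    lim <- (n - 1) * pitch / 2 + seg / 2
    ax <- seq(-lim + res / 2, lim - res / 2, res)
    covered <- matrix(FALSE, length(ax), length(ax))
    cs <- (seq_len(n) - (n + 1) / 2) * pitch
    for (cx in cs) for (cy in cs) {
      covered[abs(ax - cy) <= seg / 2, abs(ax - cx) <= seg / 2] <- TRUE
    }
    sum(covered) * res^2
  }
  for (geom in list(c(9, 18), c(6, 18))) {
    p <- geom[1]; s <- geom[2]
    expect_equal(raster_union(p, s, 5), ((5 - 1) * p + s)^2, tolerance = 0.05)
    n_big <- 1000                            # asymptotic lattice, analytic union
    reuse_oracle <- 1 - ((n_big - 1) * p + s)^2 / (n_big^2 * s^2)
    expect_equal(segment_reuse_fraction(p, s), reuse_oracle, tolerance = 0.005)
  }
  expect_error(segment_reuse_fraction(9, 6), "invalid geometry")
})

test_that("illumination wavevectors: trigonometry, bound, translation equivariance", {
  geo <- test_geometry()
  # LED directly above the field point
  expect_equal(illumination_wavevector(c(2, -1), c(2, -1), geo$grid, geo$cfg),
               c(0, 0))
  # 3 mm offset at h = 33 mm: |f| * lambda = sin(atan(3/33))
  k <- illumination_wavevector(c(3, 0), c(0, 0), geo$grid, geo$cfg)
  expect_equal(sqrt(sum(k^2)) * geo$cfg$lambda_um, sin(atan(3 / 33)),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(k^2)) * geo$cfg$lambda_um, 0.09054, tolerance = 1e-4)
  # direction-cosine bound and translation equivariance
  set.seed(42)
  for (i in 1:25) {
    led <- stats::runif(2, -20, 20); fp <- stats::runif(2, -0.5, 0.5)
    sh <- stats::runif(2, -5, 5)
    k1 <- illumination_wavevector(led, fp, geo$grid, geo$cfg)
    expect_lt(sqrt(sum(k1^2)) * geo$cfg$lambda_um, 1)
    expect_equal(k1, illumination_wavevector(led + sh, fp + sh, geo$grid, geo$cfg))
  }
})

test_that("acceptance radius follows h tan(asin(NA)) and is monotone", {
  geo <- test_geometry()
  na <- 0.23
  expect_equal(acceptance_radius(geo$grid, geo$cfg, na),
               33 * na / sqrt(1 - na^2), tolerance = 1e-12)
  expect_equal(round(acceptance_radius(geo$grid, geo$cfg, 0.23), 2), 7.80)
  expect_equal(acceptance_radius(geo$grid, geo$cfg, 1e-9), 0, tolerance = 1e-6)
  nas <- seq(0.05, 0.9, 0.05)
  expect_true(all(diff(vapply(nas, function(x)
    acceptance_radius(geo$grid, geo$cfg, x), numeric(1))) > 0))
  expect_error(acceptance_radius(geo$grid, geo$cfg, 1.1), "na_illum_max")
})

test_that("parallel illumination: cone invariant holds exhaustively and coverage is complete", {
  geo <- test_geometry()
  for (m in c(6, 8)) {
    plan <- schedule_parallel_illumination(geo$grid, geo$layout, geo$cfg, m = m)
    expect_length(plan$patterns, m^2)
    r_acc <- acceptance_radius(geo$grid, geo$cfg)
    pos <- geo$grid$positions
    # brute-force re-check over all (frame, well, LED) triples
    worst <- 0L
    for (f in seq_along(plan$patterns)) {
      lit <- pos[match(plan$patterns[[f]], pos$id), ]
      for (w in seq_len(nrow(geo$layout$centers))) {
        cw <- geo$layout$centers[w, ]
        n_in <- sum(sqrt((lit$x_mm - cw$x_mm)^2 + (lit$y_mm - cw$y_mm)^2) <= r_acc)
        worst <- max(worst, n_in)
      }
    }
    expect_lte(worst, 1L)
    # within-pattern source separation >= m pitches on each axis
    for (f in seq_along(plan$patterns)) {
      lit <- pos[match(plan$patterns[[f]], pos$id), ]
      if (nrow(lit) > 1) {
        dx <- abs(outer(lit$ix, lit$ix, `-`)); dy <- abs(outer(lit$iy, lit$iy, `-`))
        off <- row(dx) != col(dx)
        expect_true(all(pmax(dx[off], dy[off]) >= m))
      }
    }
  }
})

test_that("default m = 8 plan: 64 patterns, 49 assigned frames per well, full segment coverage", {
  geo <- test_geometry()
  plan <- schedule_parallel_illumination(geo$grid, geo$layout, geo$cfg, m = 8)
  expect_length(plan$patterns, 64)
  pm <- plan$per_well_map
  per_well <- tapply(!is.na(pm$led_id), pm$well, sum)
  expect_true(all(per_well == 49))
  # coverage: the union of assigned LEDs is exactly each well's 7 x 7 segment
  pos <- geo$grid$positions
  for (w in c("A1", "D6", "H12")) {
    cw <- geo$layout$centers[geo$layout$centers$well == w, ]
    assigned <- sort(unique(pm$led_id[pm$well == w & !is.na(pm$led_id)]))
    seg <- pos$id[abs(pos$x_mm - cw$x_mm) <= 9 + 1e-9 &
                    abs(pos$y_mm - cw$y_mm) <= 9 + 1e-9]
    expect_identical(assigned, sort(seg))
  }
})

test_that("scheduler edge cases: degenerate single-LED scan and too-small m", {
  cfg <- optical_config()
  layout <- well_layout(1, 1)
  grid <- build_led_grid(layout)
  # separation beyond the whole array degenerates to one LED per pattern
  plan <- schedule_parallel_illumination(grid, layout, cfg, m = 50)
  expect_true(all(lengths(plan$patterns) == 1))
  expect_length(plan$patterns, nrow(grid$positions))
  expect_error(schedule_parallel_illumination(grid, layout, cfg, m = 5),
               "acceptance radius")
})

test_that("plan table export lists every lit LED with its coordinates", {
  geo <- test_geometry()
  plan <- schedule_parallel_illumination(geo$grid, geo$layout, geo$cfg, m = 8)
  tab <- plan_table(plan, geo$grid)
  expect_identical(names(tab), c("frame", "led_id", "x_mm", "y_mm"))
  expect_identical(nrow(tab), sum(lengths(plan$patterns)))
  expect_identical(sort(unique(tab$frame)), seq_along(plan$patterns))
})
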
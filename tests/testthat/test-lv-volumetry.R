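make_square_stack <- function(area_mm2, thickness = 6, gap = 4,
                              phase = "ED", n_slices = 1) {
  side <- sqrt(area_mm2)
  sq <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  contour_stack(
    lapply(seq_len(n_slices), function(i) list(index = i, endo = sq)),
    slice_thickness = thickness, gap = gap, phase = phase
  )
}

test_that("polygon area: shoelace on known shapes, orientation-independent", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  gon64 <- cbind(10 * cos(theta), 10 * sin(theta))
  expect_lt(abs(polygon_area(gon64) - pi * 100) / (pi * 100), 0.005)
  expect_error(polygon_area(sq[1:2, ]), "at least 3")
})

test_that("disc summation: area times slab span, mm^3 to ml", {
  st <- make_square_stack(1000)
  expect_equal(simpson_volume(st), 10)  # 1000 mm2 x (6+4) mm = 10 ml
  tiny <- make_square_stack(1e-10)
  expect_lt(simpson_volume(tiny), 1e-9)
  # missing epicardial surface is a validation error
  expect_error(simpson_volume(st, "epi"), "missing")
})

test_that("disc summation recovers analytic spheroid volume and improves on refinement", {
  va <- 4 / 3 * pi * 25^2 * 45 / 1000
  st <- discretise_lv_ellipsoid(25, 45, slice_thickness = 2, gap = 0,
                                n_vertices = 256)
  expect_lt(abs(simpson_volume(st) - va) / va, 0.03)
  errs <- vapply(c(10, 5, 2.5, 1.25), function(h) {
    s <- discretise_lv_ellipsoid(25, 45, slice_thickness = h, gap = 0,
                                 n_vertices = 256)
    abs(simpson_volume(s) - va) / va
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("LV mass from the epicardial-endocardial shell at standard density", {
  # two square surfaces with known areas: epi 15000 mm2, endo 7000 mm2
  side_e <- sqrt(15000); side_i <- sqrt(7000)
  sl <- list(index = 1,
             endo = rbind(c(0, 0), c(side_i, 0), c(side_i, side_i),
                          c(0, side_i)),
             epi = rbind(c(0, 0), c(side_e, 0), c(side_e, side_e),
                         c(0, side_e)))
  st <- contour_stack(list(sl), 6, 4, "ED")
  # volumes 150 and 70 ml -> 80 ml myocardium -> 84 g
  expect_equal(lv_mass(st), 84)
  sl0 <- sl; sl0$epi <- sl0$endo
  expect_equal(lv_mass(contour_stack(list(sl0), 6, 4, "ED")), 0)
  # synthetic shell with analytic wall volume
  geo <- wbcvmr:::lv_ellipsoid_geometry(130, 45, 110)
  shell <- discretise_lv_ellipsoid(geo$a_ed, geo$c_ed, geo$a_epi, geo$c_epi,
                                   slice_thickness = 2, gap = 0,
                                   n_vertices = 256)
  expect_lt(abs(lv_mass(shell) - 110) / 110, 0.03)
})

test_that("DuBois body surface area evaluates the published power law", {
  expect_equal(round(dubois_bsa(180, 70), 3), 1.886)
  expect_equal(round(dubois_bsa(100, 10), 3), 0.539)
  # doubling the weight factor exactly
  expect_equal(dubois_bsa(180, 70 * 2^(1 / 0.425)),
               2 * dubois_bsa(180, 70))
  expect_error(dubois_bsa(0, 70), "positive")
  expect_error(dubois_bsa(180, -1), "positive")
})

test_that("derived metrics satisfy their defining identities", {
  geo <- wbcvmr:::lv_ellipsoid_geometry(150, 50, 120)
  ed <- discretise_lv_ellipsoid(geo$a_ed, geo$c_ed, geo$a_epi, geo$c_epi,
                                slice_thickness = 2, gap = 0)
  es <- discretise_lv_ellipsoid(geo$a_es, geo$c_es,
                                slice_thickness = 2, gap = 0, phase = "ES")
  m <- derive_metrics(ed, es, 178, 82)
  expect_equal(m$lvsv, m$lvedv - m$lvesv)
  expect_equal(m$lvef * m$lvedv, 100 * m$lvsv)
  expect_true(m$lvef >= 0 && m$lvef <= 100)
  bsa <- dubois_bsa(178, 82)
  expect_equal(m$lvedv_i, m$lvedv / bsa)
  expect_equal(m$lvm_i, m$lvm / bsa)
  # EF does not depend on body habitus
  m2 <- derive_metrics(ed, es, 150, 50)
  expect_equal(m$lvef, m2$lvef)
  # mass/volume vs the literal volume/mass convention
  m3 <- derive_metrics(ed, es, 178, 82, lvmvr = "volume_over_mass")
  expect_equal(m$lvmvr, 1 / m3$lvmvr)
  # ES larger than ED is rejected
  expect_error(derive_metrics(es, ed, 178, 82), "exceeds")
})

test_that("hand arithmetic: EF and the global function index", {
  # EDV 120 ml, ESV 40 ml
  a_ed <- (3 * 120000 / (4 * pi * 1.7))^(1 / 3)
  a_es <- (3 * 40000 / (4 * pi * 1.7))^(1 / 3)
  ed <- discretise_lv_ellipsoid(a_ed, 1.7 * a_ed,
                                a_epi = a_ed + 8, c_epi = 1.7 * a_ed + 8,
                                slice_thickness = 0.5, gap = 0)
  es <- discretise_lv_ellipsoid(a_es, 1.7 * a_es,
                                slice_thickness = 0.5, gap = 0, phase = "ES")
  m <- derive_metrics(ed, es, 175, 75)
  expect_equal(m$lvef, 66.67, tolerance = 0.005)
  # group-summary worked example: indexed inputs, scale-invariant index
  expect_equal(round(lv_gfi(45.1, 68.7, 24.9, 50.9), 2), 0.47)
  # identical phases: no stroke volume, zero EF and GFI
  m0 <- derive_metrics(ed, ed, 175, 75)
  expect_equal(m0$lvsv, 0)
  expect_equal(m0$lvef, 0)
  expect_equal(m0$lvgfi, 0)
})

test_that("volumes are invariant to in-plane rigid motion and scale cubically", {
  geo <- wbcvmr:::lv_ellipsoid_geometry(130, 45, 100)
  st <- discretise_lv_ellipsoid(geo$a_ed, geo$c_ed,
                                slice_thickness = 4, gap = 0)
  v0 <- simpson_volume(st)
  phi <- 0.7
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  moved <- st
  moved$slices <- lapply(st$slices, function(s) {
    s$endo <- sweep(s$endo %*% rot, 2, c(12, -7), `+`)
    s
  })
  expect_equal(simpson_volume(moved), v0)
  k <- 1.3
  scaled <- st
  scaled$slices <- lapply(st$slices, function(s) { s$endo <- s$endo * k; s })
  scaled$slice_thickness <- st$slice_thickness * k
  expect_equal(simpson_volume(scaled), v0 * k^3)
})

test_that("contour stacks round-trip through the JSON interchange format", {
  co <- generate_cohort(small_config(), seed = 5)
  tmp <- tempfile(fileext = ".json")
  sub <- co$stacks[1:3]
  write_contour_stacks(sub, tmp)
  back <- read_contour_stacks(tmp)
  expect_setequal(names(back), names(sub))
  pid <- names(sub)[1]
  expect_equal(simpson_volume(back[[pid]]$ED),
               simpson_volume(sub[[pid]]$ED))
  expect_equal(simpson_volume(back[[pid]]$ED, "epi"),
               simpson_volume(sub[[pid]]$ED, "epi"))
  expect_equal(back[[pid]]$ES$phase, "ES")
})
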
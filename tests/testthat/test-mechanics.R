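# Mechanical post-processing: stress/strain transforms, cycle segmentation,
# tangent moduli against analytic derivatives, adhesion normalization.

test_that("nominal stress and natural strain transforms are exact", {
  r <- stress_strain_from_raw(0, 0, area0 = 20, length0 = 50)
  expect_equal(c(r$strain, r$stress), c(0, 0))
  r2 <- stress_strain_from_raw(1, 50, area0 = 20, length0 = 50)
  expect_equal(r2$strain, log(2), tolerance = 1e-12)
  expect_equal(r2$stress, 0.05, tolerance = 1e-12)
  expect_error(stress_strain_from_raw(1, -50, 20, 50), "length")
  # strain <-> displacement round trip
  u <- seq(-20, 60, by = 5)
  eps <- stress_strain_from_raw(0, u, 20, 50)$strain
  expect_equal(displacement_from_strain(eps, 50), u, tolerance = 1e-10)
})

test_that("cycle segmentation recovers generated cycles under noise", {
  set.seed(14)
  for (nc in 1:6) {
    rec <- gen_tensile("linear", c(E = 0.02), n_cycles = nc, eps_max = 0.7)
    noisy <- rec$strain + rnorm(length(rec$strain), 0, 0.01 * 0.7)
    sc <- segment_cycles(noisy)
    expect_equal(length(sc$cycles), nc)
    expect_equal(sc$peaks, 0.7 * seq_len(nc) / nc, tolerance = 0.03)
  }
  # exact indices on the clean 4-cycle record
  rec4 <- gen_tensile("linear", c(E = 0.02))
  sc4 <- segment_cycles(rec4$strain)
  expect_equal(sc4$peaks, c(0.175, 0.35, 0.525, 0.7), tolerance = 1e-6)
  # monotone ramp: single loading segment
  expect_true(segment_cycles(seq(0, 0.7, by = 0.002))$loading_only)
  expect_warning(
    segment_cycles(c(seq(0, 0.5, 0.01), seq(0.5, 0, -0.01),
                     seq(0, 0.3, 0.01), seq(0.3, 0, -0.01))),
    "non-decreasing")
})

test_that("tangent modulus matches analytic derivatives", {
  lin <- gen_tensile("linear", c(E = 0.02))
  et_lin <- tangent_modulus(lin)
  expect_equal(et_lin$Et, rep(0.02, length(et_lin$Et)), tolerance = 1e-9)

  ex <- gen_tensile("exponential", c(a = 0.01, b = 2))
  et <- tangent_modulus(ex, window = 0.05)
  analytic <- 0.01 * 2 * exp(2 * et$strain)
  span <- range(et$strain)
  interior <- et$strain > span[1] + 0.05 * diff(span) &
    et$strain < span[2] - 0.05 * diff(span)
  expect_lt(max(abs(et$Et[interior] - analytic[interior]) /
                  analytic[interior]), 0.02)
  # anchor: Et(0.3) = a b exp(0.6) = 0.0364 MPa
  i03 <- which.min(abs(et$strain - 0.3))
  expect_equal(et$Et[i03], 0.02 * exp(2 * et$strain[i03]), tolerance = 0.02)
  expect_equal(0.01 * 2 * exp(0.6), 0.0364, tolerance = 2e-3)

  # stiffer law dominates everywhere (EF50-like vs hydrogel-like ordering)
  stiff <- gen_tensile("linear", c(E = 0.08))
  et_stiff <- tangent_modulus(stiff)
  expect_true(all(et_stiff$Et >= et_lin$Et))
})

test_that("tangent modulus guards its window and segment", {
  ex <- gen_tensile("exponential", c(a = 0.01, b = 2))
  expect_error(tangent_modulus(ex, window = 2), "window larger")
  short <- list(strain = seq(0, 0.1, length.out = 5),
                stress = seq(0, 0.002, length.out = 5),
                cycles = list(list(load = c(1, 5), unload = c(1, 5))))
  expect_error(tangent_modulus(short), "fewer than 10")
})

test_that("adhesion traces normalize by the relaxation force", {
  ad <- gen_adhesion(tack_tau = 3)
  an <- adhesion_normalize(ad$force, ad$time, ad$relax_window)
  expect_equal(an$f_relax, 2, tolerance = 1e-3)
  # normalized force magnitude is 1 at the end of relaxation
  i_end <- which.min(abs(ad$time - ad$relax_window[2]))
  expect_equal(abs(an$normalized_force[i_end]), 1, tolerance = 0.01)
  # scale invariance
  an2 <- adhesion_normalize(ad$force * 7.3, ad$time, ad$relax_window)
  expect_equal(an2$normalized_force, an$normalized_force, tolerance = 1e-12)
  # separation time tracks the decay constant: 10 s tackier delay
  slow <- gen_adhesion(tack_tau = 3 + 10 / log(20))
  an_slow <- adhesion_normalize(slow$force, slow$time, slow$relax_window)
  expect_equal(an_slow$separation_time - an$separation_time, 10,
               tolerance = 0.5)
  expect_gt(an_slow$separation_time, an$separation_time)
  # no contact: error
  expect_error(adhesion_normalize(rep(0, 100), seq(0, 99), c(10, 20)),
               "no contact")
})
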
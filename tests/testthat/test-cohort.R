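test_that("genotype draws honour Hardy-Weinberg and twin structure", {
  subj <- make_subjects(rep("singleton", 400))
  expect_true(all(draw_genotypes(subj, 0) == 0))
  expect_true(all(draw_genotypes(subj, 1) == 2))
  expect_error(draw_genotypes(subj, 1.2), "\\[0, 1\\]")

  # HWE frequencies at the allele frequency implied by a 37/101/48 split
  p <- (101 + 2 * 48) / 372
  big <- make_subjects(rep("singleton", 50000))
  set.seed(401)
  d <- draw_genotypes(big, p)
  freq <- tabulate(factor(d, 0:2), 3) / length(d)
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  expect_equal(freq, expected, tolerance = 0.02)

  # MZ concordance is exact; DZ dosage correlation is ~ 0.5 (Mendelian)
  subj2 <- make_subjects(rep(c("MZ", "DZ"), each = 2000))
  set.seed(402)
  d2 <- draw_genotypes(subj2, p)
  mz <- matrix(d2[subj2$zygosity == "MZ"], nrow = 2)
  expect_true(all(mz[1, ] == mz[2, ]))
  dz <- matrix(d2[subj2$zygosity == "DZ"], nrow = 2)
  # se of the correlation at 2000 pairs is ~0.017; allow 3.5 se
  expect_lt(abs(stats::cor(dz[1, ], dz[2, ]) - 0.5), 0.06)
  # DZ marginal distribution still HWE
  fr <- tabulate(factor(dz, 0:2), 3) / length(dz)
  expect_equal(fr, expected, tolerance = 0.02)
})

test_that("gain assignment places the dosage effect on the OFF pathway", {
  spec <- cohort_spec(off_effect = -0.08, subject_sd = 0.2,
                      family_sd = 0, seed = 1)
  set.seed(403)
  g0 <- replicate(4000, assign_gains(0, spec)$off_bipolar_gain)
  g2 <- replicate(4000, assign_gains(2, spec)$off_bipolar_gain)
  # closed form: (1 + 2 * effect) = 0.84 with mean-one lognormal noise
  expect_equal(mean(g2) / mean(g0), 0.84, tolerance = 0.02)
  # rod photoreceptor gain is dosage-independent
  set.seed(404)
  r0 <- replicate(2500, assign_gains(0, spec)$rod_pr_max)
  r2 <- replicate(2500, assign_gains(2, spec)$rod_pr_max)
  expect_gt(stats::t.test(r0, r2)$p.value, 0.01)
  # a null effect leaves all dosage groups identically distributed
  spec0 <- cohort_spec(off_effect = 0, seed = 1)
  set.seed(405)
  o0 <- replicate(2500, assign_gains(0, spec0)$off_bipolar_gain)
  o2 <- replicate(2500, assign_gains(2, spec0)$off_bipolar_gain)
  expect_gt(stats::t.test(o0, o2)$p.value, 0.01)
  expect_error(assign_gains(3, spec), "dosage")
  expect_error(cohort_spec(off_effect = -0.6, seed = 1), "negative")
})

test_that("kinship matrix matches a brute-force per-pair assembly", {
  subj <- make_subjects(c("singleton", "singleton"))
  expect_equal(build_kinship(subj), diag(2),
               ignore_attr = TRUE)
  one_mz <- make_subjects(c("MZ", "singleton"))
  K1 <- build_kinship(one_mz)
  expect_equal(K1[1, 2], 1)
  expect_equal(sum(K1) - sum(diag(K1)), 2)

  mixed <- make_subjects(c("MZ", "DZ", "singleton", "DZ", "MZ"))
  K <- build_kinship(mixed)
  # independent brute-force oracle over all pairs
  n <- nrow(mixed)
  Ko <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Ko[i, j] <-
      if (i == j) 1
      else if (mixed$family_id[i] != mixed$family_id[j]) 0
      else if (mixed$zygosity[i] == "MZ") 1 else 0.5
  }
  expect_equal(unname(K), Ko)
  expect_true(isSymmetric(K))
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-8)
  dup <- mixed; dup$subject_id[2] <- dup$subject_id[1]
  expect_error(build_kinship(dup), "duplicated")
})

test_that("cohort simulation is reproducible and structurally sound", {
  spec <- cohort_spec(n_pairs = 10, n_singletons = 3, seed = 99)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
  s <- co1$subjects
  expect_equal(nrow(s), 23)
  expect_true(all(s$age >= 18 & s$age <= 95))
  # MZ co-twins share dosage
  for (f in unique(s$family_id[s$zygosity == "MZ"])) {
    expect_equal(length(unique(s$dosage[s$family_id == f])), 1)
  }
  expect_equal(rownames(co1$kinship), s$subject_id)
})

test_that("recording sessions are deterministic and log artifacts", {
  spec <- tiny_spec(seed = 7)
  co <- simulate_cohort(spec)
  prot <- standard_protocol("iscev")[c("DA 3", "LA 3")]
  s1 <- simulate_session(co$subjects[1, ], co$gains[[1]], prot, spec,
                         seed = 1234)
  s2 <- simulate_session(co$subjects[1, ], co$gains[[1]], prot, spec,
                         seed = 1234)
  expect_identical(s1, s2)
  expect_equal(length(s1$sweeps[["DA 3"]]$RE), spec$n_sweeps)

  # noiseless, artifact-free sessions have identical sweeps per eye
  spec0 <- cohort_spec(n_pairs = 1, noise_sd = 0, drift_sd = 0,
                       artifact_rate = 0, n_sweeps = 3, seed = 5)
  co0 <- simulate_cohort(spec0)
  s0 <- simulate_session(co0$subjects[1, ], co0$gains[[1]], prot, spec0,
                         seed = 1)
  expect_identical(s0$sweeps[["DA 3"]]$RE[[1]]$voltage,
                   s0$sweeps[["DA 3"]]$RE[[3]]$voltage)

  # injected artifact count matches the metadata log
  spec_a <- cohort_spec(n_pairs = 1, artifact_rate = 0.25, n_sweeps = 10,
                        seed = 5)
  co_a <- simulate_cohort(spec_a)
  s_a <- simulate_session(co_a$subjects[1, ], co_a$gains[[1]], prot,
                          spec_a, seed = 31)
  injected <- sum(vapply(names(s_a$sweeps), function(lab) {
    sum(vapply(c("RE", "LE"), function(eye) {
      sum(vapply(s_a$sweeps[[lab]][[eye]],
                 function(sw) isTRUE(sw$meta$artifact_injected), NA))
    }, 0L))
  }, 0L))
  expect_equal(nrow(s_a$artifact_log), injected)
  expect_gt(injected, 0)
  expect_error(simulate_session(co_a$subjects[1, ], co_a$gains[[1]],
                                list(), spec_a, seed = 1), "non-empty")
})
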
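test_that("subset enumeration covers every subsystem of size >= 2", {
  set.seed(11)
  m7 <- rand_var_model(7)
  sp <- subset_phi_all(m7)
  expect_equal(nrow(sp), 120)  # 2^7 - 7 - 1
  expect_true(all(sp$size >= 2))
  expect_length(unique(sp$mask), 120)

  m2 <- rand_var_model(2)
  expect_equal(nrow(subset_phi_all(m2)), 1)
})

test_that("a fully independent system has no complexes", {
  m <- lagged_model(diag(4), diag(4), matrix(0, 4, 4))
  rep <- summarize_complexes(m)
  expect_lt(max(abs(rep$subset_phis$phi_mip)), 1e-8)
  expect_equal(rep$n_complexes, 0)
  expect_equal(rep$sum_main_phi, 0)
  expect_null(rep$max_main)
})

test_that("two independent coupled pairs are exactly the main complexes", {
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- matrix(c(0.5, 0.3, 0.3, 0.5), 2)
  A[3:4, 3:4] <- matrix(c(0.5, -0.25, 0.3, 0.5), 2)
  m <- var1_population_model(A, tau = 1)
  rep <- summarize_complexes(m)

  ckeys <- sort(rep$complexes$key)
  expect_true(all(c("1,2", "3,4") %in% ckeys))
  expect_false("1,2,3,4" %in% ckeys)  # whole system has Phi_MIP ~ 0
  mkeys <- sort(rep$main_complexes$key)
  expect_equal(mkeys, c("1,2", "3,4"))

  p12 <- rep$subset_phis$phi_mip[rep$subset_phis$key == "1,2"]
  p34 <- rep$subset_phis$phi_mip[rep$subset_phis$key == "3,4"]
  expect_equal(rep$sum_main_phi, p12 + p34, tolerance = 1e-12)
  expect_equal(rep$max_main$phi_mip, max(p12, p34), tolerance = 1e-12)
})

test_that("complex detection logic follows the definition on a crafted table", {
  set.seed(13)
  m <- rand_var_model(3)
  sp <- subset_phi_all(m)
  # phi strictly increasing with size: only the whole system is a complex
  sp$phi_mip[sp$size == 2] <- c(0.01, 0.02, 0.03)
  sp$phi_mip[sp$size == 3] <- 0.1
  cx <- find_complexes(sp)
  expect_equal(cx$key, "1,2,3")

  # all phi ~ 0: no complexes
  sp$phi_mip <- rep(1e-14, 4)
  expect_equal(nrow(find_complexes(sp)), 0)

  # incomplete table is rejected
  expect_error(find_complexes(sp[-1, ]), "incomplete")
})

test_that("direct-definition main complexes are always found by the shortcut", {
  # The contains-no-other-complex shortcut and the beats-every-subset
  # direct definition are not equivalent for Phi* in general, but one
  # containment is a theorem: a complex that beats all its subsets cannot
  # contain another complex, so direct-main implies shortcut-main.
  # (Pairwise disjointness likewise does not follow from the definitions:
  # overlapping main complexes occur on generic Gaussian models.)
  set.seed(17)
  for (i in 1:25) {
    m <- rand_var_model(sample(3:5, 1))
    sp <- subset_phi_all(m)
    cx <- find_complexes(sp)
    mc_short <- find_main_complexes(cx)
    mc_direct <- find_main_complexes(cx, sp, method = "direct")
    expect_true(all(mc_direct$key %in% mc_short$key))
    # internal consistency of the shortcut: every main complex is a
    # complex and contains no other complex
    expect_true(all(mc_short$key %in% cx$key))
    for (mk in mc_short$mask) {
      inside <- cx$mask[bitwAnd(cx$mask, mk) == cx$mask & cx$mask != mk]
      expect_length(inside, 0)
    }
  }
})

test_that("restricting a model commutes with computing Phi on sub-blocks", {
  set.seed(19)
  m <- rand_var_model(5)
  sp <- subset_phi_all(m)
  for (key in c("1,3", "2,4,5", "1,2,3,4")) {
    nodes <- as.integer(strsplit(key, ",")[[1]])
    sub <- restrict_model(m, nodes)
    direct <- mip_search(sub, per_partition = FALSE)
    expect_equal(sp$phi_mip[sp$key == key], direct$phi_mip, tolerance = 1e-9)
  }
})

test_that("a strongly globally coupled system keeps the whole set as its core", {
  A <- matrix(0.12, 5, 5)
  diag(A) <- 0.4
  m <- var1_population_model(A, tau = 1)
  rep <- summarize_complexes(m)
  expect_equal(rep$max_main$nodes, 1:5)
  expect_equal(rep$n_main_complexes, 1)
})
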
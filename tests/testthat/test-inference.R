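# Reversible-jump MCMC, stepping-stone marginal likelihoods, model
# comparison and the clade-analysis orchestrator.

small_sim <- function(n = 120, q_mn = 0.4, q_nm = 0.4, seed = 1) {
  tr <- simulate_tree(n, seed = seed)
  simulate_history(tr, rate_model(q_mn, q_nm), seed = seed + 1)
}

test_that("the sampler trace is bit-identical under a fixed seed", {
  sim <- small_sim(seed = 10)
  a <- sample_posterior(sim$atree, gens_per_tree = 400, thin = 5, seed = 77)
  b <- sample_posterior(sim$atree, gens_per_tree = 400, thin = 5, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sample_posterior(sim$atree, gens_per_tree = 400, thin = 5, seed = 78)
  expect_false(identical(as.data.frame(a)$q_mn, as.data.frame(c)$q_mn))
})

test_that("prior-only sampling recovers the hyperprior", {
  at <- annotate(read_tree("(A:1,B:1);"), c(A = "marine", B = "non_marine"))
  post <- sample_posterior(at, gens_per_tree = 100000, burn_in = 0.1,
                           thin = 40, seed = 123, beta = 0)
  d <- as.data.frame(post)
  expect_gt(nrow(d), 2000)
  # m ~ Uniform(0, 2)
  p_m <- suppressWarnings(stats::ks.test(unique(d$m), "punif", 0, 2))$p.value
  expect_gt(p_m, 0.01)
  # q | m ~ Exponential(mean m): probability integral transform is uniform
  u <- stats::pexp(d$q_mn, rate = 1 / d$m)
  p_q <- suppressWarnings(stats::ks.test(unique(u), "punif"))$p.value
  expect_gt(p_q, 0.01)
  # model indicator spends about half its time in each model
  expect_gt(mean(d$model == "equal"), 0.45)
  expect_lt(mean(d$model == "equal"), 0.55)
})

test_that("posteriors concentrate on the simulation truth", {
  # symmetric truth: the equal-rates model is favoured across chains
  p_eq <- vapply(1:3, function(s) {
    sim <- small_sim(n = 200, q_mn = 0.5, q_nm = 0.5, seed = 10 + s)
    post <- sample_posterior(sim$atree, gens_per_tree = 1200,
                             seed = 30 + s)
    summary(post)$p_equal
  }, 1)
  expect_true(all(p_eq > 0.5))
  # strongly asymmetric truth: credible interval of the ratio excludes 1
  sim <- small_sim(n = 200, q_mn = 2, q_nm = 0.1, seed = 99)
  post <- sample_posterior(sim$atree, gens_per_tree = 2000, seed = 101)
  s <- summary(post)
  expect_gt(s$ratio_lo, 1)
  expect_lt(s$p_equal, 0.1)
})

test_that("cycle and swap modes both traverse a tree set", {
  sim <- small_sim(n = 60, seed = 55)
  ts <- make_tree_set(sim$atree, n = 4, jitter_sd = 0.2, seed = 56)
  cyc <- sample_posterior(ts, gens_per_tree = 300, thin = 10, seed = 57)
  expect_setequal(unique(as.data.frame(cyc)$tree), 1:4)
  swp <- sample_posterior(ts, gens_per_tree = 2000, thin = 10, seed = 58,
                          tree_mode = "swap")
  expect_gt(length(unique(as.data.frame(swp)$tree)), 1L)
})

test_that("stepping stone matches quadrature and is self-consistent", {
  # likelihood identically 1 (no data): logZ = 0 +/- 0
  s0 <- stepping_stone(NULL, n_stones = 5, chain_length = 200, seed = 1)
  expect_equal(s0$logZ, 0)
  expect_equal(s0$se, 0)

  # fixed-hyperparameter equal-rates model on a 4-tip tree against 1-D
  # adaptive quadrature of integral L(q) Exp(q; mean 1) dq
  at <- annotate(read_tree("((A:0.6,B:1.2):0.4,(C:0.8,D:0.3):0.7);"),
                 c(A = "marine", B = "non_marine", C = "marine",
                   D = "marine"))
  quad <- stats::integrate(function(q) {
    vapply(q, function(qq) exp(tree_loglik(at, rate_model(qq, qq))), 1) *
      stats::dexp(q, 1)
  }, 0, Inf, rel.tol = 1e-10)
  lz_quad <- log(quad$value)
  ss <- stepping_stone(tree_set(at), n_stones = 20, chain_length = 1000,
                       fixed_m = 1, rj = FALSE, eq_init = TRUE, seed = 5)
  expect_lt(abs(ss$logZ - lz_quad), 3 * ss$se + 0.01)
  # more stones agree within combined error
  ss2 <- stepping_stone(tree_set(at), n_stones = 50, chain_length = 1000,
                        fixed_m = 1, rj = FALSE, eq_init = TRUE, seed = 6)
  expect_lt(abs(ss$logZ - ss2$logZ), 3 * sqrt(ss$se^2 + ss2$se^2) + 0.01)
  # the beta ladder is a valid 0 = b0 < ... < bK = 1 grid
  expect_equal(ss$stones$beta_from[1], 0)
  expect_equal(ss$stones$beta_to[nrow(ss$stones)], 1)
  expect_true(all(diff(c(ss$stones$beta_from, 1)) > 0))
})

test_that("Bayes-factor comparison is antisymmetric and thresholded", {
  cmp <- compare_models(-100, -110)
  expect_equal(cmp$log_bf, 20)
  expect_equal(cmp$favours, "A")
  expect_equal(compare_models(-110, -100)$log_bf, -20)
  expect_equal(compare_models(-110, -100)$favours, "B")
  eq <- compare_models(-50, -50)
  expect_equal(eq$log_bf, 0)
  expect_equal(eq$favours, "neither")
  expect_error(compare_models(Inf, 0), "finite")
})

test_that("clade analysis applies eligibility rules and reports", {
  sim_big <- small_sim(n = 60, q_mn = 0.6, q_nm = 0.6, seed = 201)
  sim_small <- small_sim(n = 30, seed = 202)
  tr_uni <- simulate_tree(60, seed = 203)
  uni <- annotated_tree(tr_uni,
                        stats::setNames(rep("marine", 60),
                                        tr_uni$tip.label))
  out <- withr::local_tempfile(fileext = ".json")
  rep <- run_clade_analysis(list(
    clades = list(
      good = list(trees = tree_set(sim_big$atree)),
      small = list(trees = tree_set(sim_small$atree)),
      monomorphic = list(trees = tree_set(uni))
    ),
    min_tips = 50,
    mcmc = list(gens_per_tree = 400, burn_in = 0.5, thin = 5),
    events = TRUE,
    seed = 9,
    out = out
  ))
  expect_equal(rep$clades$small$status, "skipped")
  expect_match(rep$clades$small$reason, "fewer than 50 tips")
  expect_equal(rep$clades$monomorphic$status, "skipped")
  expect_match(rep$clades$monomorphic$reason, "single habitat")
  expect_equal(rep$clades$good$status, "analysed")
  expect_true(is.finite(rep$clades$good$posterior$q_mn_mean))
  expect_true(!is.null(rep$clades$good$transitions))
  # report written as valid JSON
  back <- jsonlite::read_json(out)
  expect_equal(back$clades$good$status, "analysed")
  expect_true(any(grepl("skipped", unlist(back$log))))
})

test_that("sensitivity subsampling returns the requested grid", {
  sim <- small_sim(n = 60, q_mn = 0.6, q_nm = 0.6, seed = 301)
  rep <- run_clade_analysis(list(
    clades = list(cl = list(trees = tree_set(sim$atree))),
    min_tips = 50,
    mcmc = list(gens_per_tree = 300, burn_in = 0.5, thin = 5),
    events = FALSE,
    subsample = list(habitats = "marine", fractions = c(0.1, 0.3),
                     replicates = 2, gens_per_tree = 200),
    seed = 10
  ))
  sens <- rep$clades$cl$sensitivity
  expect_equal(nrow(sens), 4L)
  expect_setequal(unique(sens$fraction), c(0.1, 0.3))
  expect_true(all(is.finite(sens$q_mn_mean)))
})

test_that("YAML configs drive the orchestrator end to end", {
  dir <- withr::local_tempdir()
  man <- study_like_bundle(
    dir, clades = list(cl = list(n = 55, q_mn = 0.8, q_nm = 0.4)),
    n_trees = 2, jitter_sd = 0.05, seed = 21
  )
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    clades = list(cl = list(trees = man$clades$cl$files$trees,
                            habitat = man$clades$cl$files$habitat)),
    min_tips = 50,
    mcmc = list(gens_per_tree = 300, burn_in = 0.5, thin = 5),
    events = FALSE,
    seed = 3
  ), cfg)
  rep <- run_clade_analysis(cfg)
  expect_equal(rep$clades$cl$status, "analysed")
  expect_equal(rep$clades$cl$n_trees, 2L)
})
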
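# Bayesian estimation of habitat transition rates over tree sets:
# reversible-jump MCMC under an exponential hyperprior (mean ~ U(0, 2)),
# stepping-stone marginal likelihoods and Bayes-factor model comparison.

#' Prior specification for rate inference
#'
#' The hyperprior scheme: the exponential-prior mean `m` is itself drawn
#' uniformly on `(0, m_max)` (default 2), each free rate is
#' `Exponential(mean = m)`, and the reversible-jump indicator puts equal
#' prior mass on the equal-rates and unequal-rates models.
#'
#' @param m_max upper bound of the uniform hyperprior on the exponential
#'   mean.
#' @param p_equal prior probability of the equal-rates model.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(m_max = 2, p_equal = 0.5) {
  stopifnot(m_max > 0, p_equal > 0, p_equal < 1)
  structure(list(m_max = m_max, p_equal = p_equal), class = "prior_spec")
}

# Per-tree precomputation shared by every likelihood evaluation: integer tip
# states, per-edge regime index (background is the last regime) and a cached
# post-order edge ordering.
prep_tree_data <- function(trees, clade_defs = NULL) {
  regimes <- if (is.null(clade_defs)) "background"
             else c(names(clade_defs), "background")
  preps <- lapply(trees, function(at) {
    tree <- at$tree
    if (!ape::is.rooted(tree)) {
      stop_habtrans("all trees must be rooted for inference")
    }
    reg <- if (is.null(clade_defs)) rep(1L, nrow(tree$edge))
           else match(paint_regimes(tree, clade_defs, "background"), regimes)
    list(tree = tree, tip = tip_states_int(at), reg = reg,
         len = tree$edge.length, ord = postorder_edges(tree))
  })
  attr(preps, "regimes") <- regimes
  preps
}

# Log-likelihood of one prepared tree under per-regime rates (R x 2 matrix).
ll_prepared <- function(prep, rates, root = "equal", root_p = NULL) {
  q1 <- rates[prep$reg, 1L]
  q2 <- rates[prep$reg, 2L]
  pr <- if (root == "stationary") {
    bg <- nrow(rates)
    s <- rates[bg, 1L] + rates[bg, 2L]
    if (s <= 0) c(0.5, 0.5) else c(rates[bg, 2L], rates[bg, 1L]) / s
  } else if (root == "fixed") {
    c(root_p, 1 - root_p)
  } else {
    c(0.5, 0.5)
  }
  P <- mk2_edge_P(q1, q2, prep$len)
  mk2_pruning(prep$tree, prep$tip, P, pr, ord = prep$ord)$loglik
}

# log prior density of the free rates given hyper mean m.
rate_prior_lp <- function(rates, eq, m) {
  lp <- 0
  for (r in seq_len(nrow(rates))) {
    lp <- lp + stats::dexp(rates[r, 1L], rate = 1 / m, log = TRUE)
    if (!eq[r]) lp <- lp + stats::dexp(rates[r, 2L], rate = 1 / m, log = TRUE)
  }
  lp
}

# Core Metropolis-within-reversible-jump engine over a prepared tree list.
# `beta` tempers the likelihood (power posterior), enabling both ordinary
# posterior sampling (beta = 1), prior sampling (beta = 0) and
# stepping-stone stones. Proposal scales are auto-tuned toward 20-40%
# acceptance during burn-in, then frozen. Randomness uses the ambient RNG;
# callers seed via with_seed().
mcmc_engine <- function(preps, prior, gens, burn_frac = 0.5, thin = 10L,
                        beta = 1, rj = TRUE, fixed_m = NULL,
                        tree_mode = c("cycle", "swap"),
                        tree_update_every = 10L, root = "equal",
                        root_p = NULL, tune = TRUE, sigma = 0.5,
                        delta_m = 0.3, sigma_rj = 0.5, init_state = NULL,
                        eq_init = TRUE) {
  tree_mode <- match.arg(tree_mode)
  no_data <- is.null(preps) || length(preps) == 0L
  R <- if (no_data) 1L else length(attr(preps, "regimes"))
  n_trees <- if (no_data) 1L else length(preps)
  p_eq <- prior$p_equal
  lp_eq_ratio <- log((1 - p_eq) / p_eq)  # split move model-prior term

  ll_of <- function(tree_i, rates) {
    if (no_data) return(0)
    ll_prepared(preps[[tree_i]], rates, root, root_p)
  }

  # initial state
  if (!is.null(init_state)) {
    m <- init_state$m
    rates <- init_state$rates
    eq <- init_state$eq
    tree_i <- init_state$tree_i
  } else {
    m <- if (is.null(fixed_m)) runif(1, 0, prior$m_max) else fixed_m
    eq <- rep(isTRUE(eq_init), R)
    q0 <- rexp(R, rate = 1 / m)
    rates <- cbind(q0, ifelse(eq, q0, rexp(R, rate = 1 / m)))
    tree_i <- 1L
  }
  if (!is.null(fixed_m)) m <- fixed_m
  ll_cur <- ll_of(tree_i, rates)

  acc <- c(m = 0L, rate = 0L)
  try <- c(m = 0L, rate = 0L)
  tuning_on <- tune

  # recorded draws
  rec_gen <- integer(0)
  rec <- list()

  one_gen <- function() {
    # hyper-mean update (prior-only: the likelihood does not involve m)
    if (is.null(fixed_m)) {
      m2 <- m + runif(1, -delta_m, delta_m)
      try["m"] <<- try["m"] + 1L
      if (m2 > 0 && m2 < prior$m_max) {
        lr <- rate_prior_lp(rates, eq, m2) - rate_prior_lp(rates, eq, m)
        if (is.finite(lr) && log(runif(1)) < lr) {
          m <<- m2
          acc["m"] <<- acc["m"] + 1L
        }
      }
    }
    # sliding-window updates on log rates
    for (r in seq_len(R)) {
      csets <- if (eq[r]) list(c(1L, 2L)) else list(1L, 2L)
      for (cs in csets) {
        q <- rates[r, cs[1L]]
        q2 <- q * exp(rnorm(1, 0, sigma))
        rates2 <- rates
        rates2[r, cs] <- q2
        ll2 <- ll_of(tree_i, rates2)
        lacc <- beta * (ll2 - ll_cur) +
          stats::dexp(q2, 1 / m, log = TRUE) -
          stats::dexp(q, 1 / m, log = TRUE) + log(q2 / q)
        try["rate"] <<- try["rate"] + 1L
        if (is.finite(lacc) && log(runif(1)) < lacc) {
          rates <<- rates2
          ll_cur <<- ll2
          acc["rate"] <<- acc["rate"] + 1L
        }
      }
    }
    # reversible-jump split/merge per regime
    if (rj) {
      for (r in seq_len(R)) {
        if (eq[r]) {
          u <- rnorm(1, 0, sigma_rj)
          q <- rates[r, 1L]
          rates2 <- rates
          rates2[r, ] <- c(q * exp(u), q * exp(-u))
          ll2 <- ll_of(tree_i, rates2)
          lacc <- beta * (ll2 - ll_cur) +
            stats::dexp(rates2[r, 1L], 1 / m, log = TRUE) +
            stats::dexp(rates2[r, 2L], 1 / m, log = TRUE) -
            stats::dexp(q, 1 / m, log = TRUE) +
            lp_eq_ratio -
            stats::dnorm(u, 0, sigma_rj, log = TRUE) + log(2 * q)
          if (is.finite(lacc) && log(runif(1)) < lacc) {
            rates <<- rates2
            eq[r] <<- FALSE
            ll_cur <<- ll2
          }
        } else {
          q1 <- rates[r, 1L]
          q2 <- rates[r, 2L]
          q <- sqrt(q1 * q2)
          u <- 0.5 * log(q1 / q2)
          rates2 <- rates
          rates2[r, ] <- q
          ll2 <- ll_of(tree_i, rates2)
          lacc <- beta * (ll2 - ll_cur) +
            stats::dexp(q, 1 / m, log = TRUE) -
            stats::dexp(q1, 1 / m, log = TRUE) -
            stats::dexp(q2, 1 / m, log = TRUE) -
            lp_eq_ratio +
            stats::dnorm(u, 0, sigma_rj, log = TRUE) - log(2 * q)
          if (is.finite(lacc) && log(runif(1)) < lacc) {
            rates <<- rates2
            eq[r] <<- TRUE
            ll_cur <<- ll2
          }
        }
      }
    }
  }

  retune <- function() {
    if (try["rate"] > 0L) {
      ar <- acc["rate"] / try["rate"]
      if (ar > 0.4) sigma <<- sigma * 1.25
      if (ar < 0.2) sigma <<- max(sigma / 1.25, 1e-3)
    }
    if (try["m"] > 0L) {
      am <- acc["m"] / try["m"]
      if (am > 0.4) delta_m <<- min(delta_m * 1.25, prior$m_max)
      if (am < 0.2) delta_m <<- max(delta_m / 1.25, 1e-3)
    }
    acc[] <<- 0L
    try[] <<- 0L
  }

  record <- function(g) {
    rec_gen <<- c(rec_gen, g)
    rec[[length(rec) + 1L]] <<- c(tree_i, m, ll_cur,
                                  as.numeric(!eq), t(rates))
  }

  gen_global <- 0L
  if (tree_mode == "cycle" && !no_data) {
    burn_gens <- floor(burn_frac * gens)
    for (ti in seq_len(n_trees)) {
      tree_i <- ti
      ll_cur <- ll_of(tree_i, rates)
      for (g in seq_len(gens)) {
        gen_global <- gen_global + 1L
        one_gen()
        if (tuning_on && ti == 1L && g <= burn_gens && g %% 50L == 0L) {
          retune()
        }
        if (g > burn_gens && g %% thin == 0L) record(gen_global)
      }
      tuning_on <- FALSE
    }
  } else {
    burn_gens <- floor(burn_frac * gens)
    for (g in seq_len(gens)) {
      gen_global <- gen_global + 1L
      one_gen()
      if (!no_data && n_trees > 1L && g %% tree_update_every == 0L) {
        j <- sample.int(n_trees, 1L)
        if (j != tree_i) {
          ll_j <- ll_of(j, rates)
          if (log(runif(1)) < beta * (ll_j - ll_cur)) {
            tree_i <- j
            ll_cur <- ll_j
          }
        }
      }
      if (tuning_on && g <= burn_gens && g %% 50L == 0L) retune()
      if (g == burn_gens) tuning_on <- FALSE
      if (g > burn_gens && g %% thin == 0L) record(gen_global)
    }
  }

  if (sum(try) > 0L && sum(acc) == 0L && gens >= 200L) {
    warning("zero proposal acceptance over the diagnostic window ",
            "(sigma = ", signif(sigma, 3), ", delta_m = ",
            signif(delta_m, 3), ")")
  }

  regimes <- if (no_data) "background" else attr(preps, "regimes")
  draws <- as.data.frame(do.call(rbind, rec))
  if (nrow(draws) > 0L) {
    base <- c("tree", "m", "loglik")
    if (R == 1L) {
      names(draws) <- c(base, "unequal", "q_mn", "q_nm")
      draws$model <- ifelse(draws$unequal > 0.5, "unequal", "equal")
    } else {
      names(draws) <- c(base, paste0("unequal_", regimes),
                        as.vector(rbind(paste0("q_mn_", regimes),
                                        paste0("q_nm_", regimes))))
      for (rg in regimes) {
        draws[[paste0("model_", rg)]] <-
          ifelse(draws[[paste0("unequal_", rg)]] > 0.5, "unequal", "equal")
      }
    }
    draws$gen <- rec_gen
  }
  list(draws = draws,
       state = list(m = m, rates = rates, eq = eq, tree_i = tree_i,
                    loglik = ll_cur),
       scales = c(sigma = sigma, delta_m = delta_m, sigma_rj = sigma_rj))
}

#' Sample the posterior of habitat transition rates
#'
#' Metropolis-within-reversible-jump MCMC over a set of trees: sliding
#' window proposals on log rates and on the exponential hyper-mean `m`, a
#' split/merge reversible-jump move between the equal-rates and
#' unequal-rates models (merge to the geometric mean; split by factors
#' `exp(+/-u)`, `u ~ N(0, sigma_rj)`, with the standard Jacobian), and —
#' for tree sets — either the study schedule of a fixed number of
#' generations per tree (`tree_mode = "cycle"`, the default) or
#' Metropolis-accepted uniform tree swaps (`"swap"`). Proposal scales are
#' auto-tuned to 20-40% acceptance during burn-in, then frozen. The trace
#' is deterministic given `seed`.
#'
#' @param trees a [tree_set()] (or a single `annotated_tree`).
#' @param model_space `"homogeneous"` (one rate regime) or
#'   `"heterogeneous"` (separate rates per clade in `clade_defs` plus a
#'   background regime).
#' @param clade_defs named list of tip sets (heterogeneous space only).
#' @param prior a [prior_spec()].
#' @param gens_per_tree generations per tree in cycle mode (total
#'   generations in swap mode).
#' @param burn_in fraction of each tree's generations discarded.
#' @param thin record every `thin`-th generation.
#' @param seed integer seed.
#' @param root,root_p root policy as in [tree_loglik()].
#' @param tree_mode `"cycle"` or `"swap"` (see above).
#' @param rj enable the reversible-jump move (otherwise the model indicator
#'   stays at its initial value: `eq_init`).
#' @param eq_init start (and with `rj = FALSE`, stay) in the equal-rates
#'   model.
#' @param fixed_m fix the hyper-mean to this value instead of sampling it.
#' @param beta likelihood tempering exponent (1 = posterior; 0 = prior).
#' @return object of class `posterior_sample`: a data.frame of thinned
#'   post-burn-in draws (`gen`, `tree`, `m`, `loglik`, and per regime the
#'   model indicator and rates `q_mn`, `q_nm`), with sampler metadata in
#'   attributes.
#' @export
sample_posterior <- function(trees,
                             model_space = c("homogeneous", "heterogeneous"),
                             clade_defs = NULL, prior = prior_spec(),
                             gens_per_tree = 2000L, burn_in = 0.5,
                             thin = 10L, seed = NULL, root = "equal",
                             root_p = NULL, tree_mode = c("cycle", "swap"),
                             rj = TRUE, eq_init = TRUE, fixed_m = NULL,
                             beta = 1) {
  model_space <- match.arg(model_space)
  tree_mode <- match.arg(tree_mode)
  if (inherits(trees, "annotated_tree")) trees <- tree_set(trees)
  stopifnot(inherits(trees, "tree_set"))
  if (model_space == "heterogeneous" && is.null(clade_defs)) {
    stop_habtrans("heterogeneous model space needs clade_defs")
  }
  if (model_space == "homogeneous") clade_defs <- NULL
  preps <- prep_tree_data(trees, clade_defs)
  res <- with_seed(seed, mcmc_engine(
    preps, prior, gens = gens_per_tree, burn_frac = burn_in, thin = thin,
    beta = beta, rj = rj, fixed_m = fixed_m, tree_mode = tree_mode,
    root = root, root_p = root_p, eq_init = eq_init
  ))
  draws <- res$draws
  attr(draws, "regimes") <- attr(preps, "regimes")
  attr(draws, "settings") <- list(
    model_space = model_space, gens_per_tree = gens_per_tree,
    burn_in = burn_in, thin = thin, seed = seed, root = root,
    tree_mode = tree_mode, rj = rj, fixed_m = fixed_m, beta = beta,
    n_trees = length(trees), scales = res$scales
  )
  class(draws) <- c("posterior_sample", "data.frame")
  draws
}

#' @export
print.posterior_sample <- function(x, ...) {
  s <- attr(x, "settings")
  cat("posterior_sample:", nrow(x), "draws,", s$model_space, "model space,",
      s$n_trees, "tree(s)\n")
  invisible(x)
}

#' Summarize a posterior sample
#'
#' Posterior means and 95% credible intervals of the directional rates, the
#' normalized-matrix global rate (`2 q_mn q_nm / (q_mn + q_nm)`, the
#' expected transitions per unit branch length at stationarity), the rate
#' ratio, and the posterior probability of the equal-rates model. For
#' heterogeneous samples one row per regime.
#'
#' @param object a `posterior_sample`.
#' @param ... unused.
#' @return data.frame, one row per regime.
#' @export
summary.posterior_sample <- function(object, ...) {
  regimes <- attr(object, "regimes")
  d <- as.data.frame(object)
  one <- function(q1, q2, uneq, rg) {
    gr <- ifelse(q1 + q2 > 0, 2 * q1 * q2 / (q1 + q2), 0)
    ratio <- q1 / q2
    data.frame(
      regime = rg,
      q_mn_mean = mean(q1),
      q_mn_lo = stats::quantile(q1, 0.025, names = FALSE),
      q_mn_hi = stats::quantile(q1, 0.975, names = FALSE),
      q_nm_mean = mean(q2),
      q_nm_lo = stats::quantile(q2, 0.025, names = FALSE),
      q_nm_hi = stats::quantile(q2, 0.975, names = FALSE),
      global_rate_mean = mean(gr),
      ratio_lo = stats::quantile(ratio, 0.025, names = FALSE),
      ratio_hi = stats::quantile(ratio, 0.975, names = FALSE),
      p_equal = mean(uneq < 0.5)
    )
  }
  if (length(regimes) == 1L && !is.null(d$q_mn)) {
    out <- one(d$q_mn, d$q_nm, d$unequal, regimes)
  } else {
    out <- do.call(rbind, lapply(regimes, function(rg) {
      one(d[[paste0("q_mn_", rg)]], d[[paste0("q_nm_", rg)]],
          d[[paste0("unequal_", rg)]], rg)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood of a model space by the
#' stepping-stone method: a ladder of power posteriors at
#' `beta_k = (k/K)^(1/alpha)` (`alpha = 0.4`: Beta(0.4, 1) quantile
#' spacing), each stone contributing the log mean of
#' `likelihood^(beta_k - beta_{k-1})` over samples drawn at
#' `beta_{k-1}`. The prior stone (`beta = 0`) is sampled i.i.d. directly;
#' subsequent stones run short chains initialized from the previous stone.
#' The Monte-Carlo standard error is the delta-method sum over stones.
#'
#' @inheritParams sample_posterior
#' @param n_stones number of stones `K` (study setting: 50).
#' @param chain_length generations per stone (study setting: 5000).
#' @param alpha spacing exponent for the beta ladder.
#' @param burn_frac per-stone burn-in fraction.
#' @return object of class `stepping_stone`: list with `logZ`, `se` and the
#'   per-stone table `stones`.
#' @export
stepping_stone <- function(trees,
                           model_space = c("homogeneous", "heterogeneous"),
                           clade_defs = NULL, prior = prior_spec(),
                           n_stones = 50L, chain_length = 5000L,
                           alpha = 0.4, seed = NULL, root = "equal",
                           root_p = NULL, rj = TRUE, eq_init = TRUE,
                           fixed_m = NULL, thin = 5L, burn_frac = 0.2) {
  model_space <- match.arg(model_space)
  if (!is.null(trees)) {
    if (inherits(trees, "annotated_tree")) trees <- tree_set(trees)
    stopifnot(inherits(trees, "tree_set"))
    if (model_space == "homogeneous") clade_defs <- NULL
    preps <- prep_tree_data(trees, clade_defs)
  } else {
    preps <- NULL  # likelihood identically 1
  }
  K <- n_stones
  betas <- (seq(0L, K) / K)^(1 / alpha)
  R <- if (is.null(preps)) 1L else length(attr(preps, "regimes"))
  n_trees <- if (is.null(preps)) 1L else length(preps)
  n_rec <- max(20L, floor(chain_length / thin))

  with_seed(seed, {
    contribs <- numeric(K)
    vars <- numeric(K)
    state <- NULL
    for (k in seq_len(K)) {
      b_prev <- betas[k]
      b_next <- betas[k + 1L]
      d <- b_next - b_prev
      if (k == 1L) {
        # prior stone: i.i.d. draws
        lliks <- vapply(seq_len(n_rec), function(i) {
          m <- if (is.null(fixed_m)) runif(1, 0, prior$m_max) else fixed_m
          eq <- if (rj) runif(R) < prior$p_equal else rep(eq_init, R)
          q1 <- rexp(R, 1 / m)
          q2 <- ifelse(eq, q1, rexp(R, 1 / m))
          ti <- sample.int(n_trees, 1L)
          if (is.null(preps)) 0
          else ll_prepared(preps[[ti]], cbind(q1, q2), root, root_p)
        }, 1)
      } else {
        res <- mcmc_engine(
          preps, prior, gens = chain_length, burn_frac = burn_frac,
          thin = thin, beta = b_prev, rj = rj, fixed_m = fixed_m,
          tree_mode = "swap", root = root, root_p = root_p,
          init_state = state, eq_init = eq_init
        )
        state <- res$state
        lliks <- res$draws$loglik
      }
      if (any(!is.finite(lliks) & lliks > 0)) {
        stop_habtrans("non-finite contribution at stone ", k)
      }
      w <- d * lliks
      mx <- max(w)
      ew <- exp(w - mx)
      contribs[k] <- mx + log(mean(ew))
      vars[k] <- stats::var(ew) / (length(ew) * mean(ew)^2)
      if (!is.finite(contribs[k])) {
        stop_habtrans("non-finite contribution at stone ", k)
      }
    }
    structure(
      list(logZ = sum(contribs), se = sqrt(sum(vars)),
           stones = data.frame(beta_from = betas[-(K + 1L)],
                               beta_to = betas[-1L], contrib = contribs,
                               var = vars)),
      class = "stepping_stone"
    )
  })
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("stepping_stone: logZ = %.4f +/- %.4f (%d stones)\n",
              x$logZ, x$se, nrow(x$stones)))
  invisible(x)
}

#' Bayes-factor model comparison
#'
#' `logBF = 2 x (logZ_a - logZ_b)`; values of `threshold` (default 10) or
#' more favour model A. Antisymmetric under swapping the arguments.
#'
#' @param logZ_a,logZ_b stepping-stone results (from [stepping_stone()]) or
#'   bare log marginal likelihoods; conventionally A = heterogeneous,
#'   B = homogeneous.
#' @param threshold decision threshold on the log Bayes factor.
#' @return object of class `model_comparison`: list with `logZ_a`,
#'   `logZ_b`, `log_bf`, `se` (combined MC error of the difference, when
#'   available), `threshold` and `favours` (`"A"`, `"B"` or `"neither"`).
#' @export
compare_models <- function(logZ_a, logZ_b, threshold = 10) {
  get_z <- function(x) {
    if (inherits(x, "stepping_stone")) c(x$logZ, x$se) else c(as.numeric(x), NA)
  }
  a <- get_z(logZ_a)
  b <- get_z(logZ_b)
  if (!is.finite(a[1L]) || !is.finite(b[1L])) {
    stop_habtrans("log marginal likelihoods must be finite")
  }
  log_bf <- 2 * (a[1L] - b[1L])
  se <- if (anyNA(c(a[2L], b[2L]))) NA_real_ else 2 * sqrt(a[2L]^2 + b[2L]^2)
  favours <- if (log_bf >= threshold) "A"
             else if (-log_bf >= threshold) "B"
             else "neither"
  structure(list(logZ_a = a[1L], logZ_b = b[1L], log_bf = log_bf, se = se,
                 threshold = threshold, favours = favours),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("log Bayes factor = %.2f (threshold %.1f): favours %s\n",
              x$log_bf, x$threshold,
              switch(x$favours, A = "model A", B = "model B", "neither")))
  invisible(x)
}
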
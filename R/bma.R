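# MR-BMA: Bayesian model averaging over candidate risk factors scored on
# instrument-level associations.

#' Build the standardised MR-BMA design
#'
#' Standardises a joint multi-exposure instrument set for Bayesian model
#' averaging: response `y_j = b_Yj / se_Yj`, predictors
#' `x_jk = b_Xjk / se_Yj`, with predictor columns scaled to unit variance so
#' prior shrinkage acts evenly across traits. Also records the pairwise
#' predictor correlation matrix used for pruning.
#'
#' @param mset An `mvmr_set` from [build_mvmr_set()], or a list with elements
#'   `data` (tibble with `variant_id`, `b_y`, `se_y`, `b_x_k` columns) and
#'   `exposure_ids`.
#' @param scale_columns Scale predictor columns to unit variance (default
#'   `TRUE`).
#' @return A `bma_input` list: `y`, `X`, `variant_ids`, `trait_ids`,
#'   `correlation`, `scales`.
#' @export
bma_input <- function(mset, scale_columns = TRUE) {
  K <- length(mset$exposure_ids)
  X <- as.matrix(mset$data[paste0("b_x_", seq_len(K))])
  se_y <- mset$data$se_y
  y <- mset$data$b_y / se_y
  X <- X / se_y
  scales <- rep(1, K)
  if (scale_columns) {
    scales <- apply(X, 2, sd)
    scales[scales == 0] <- 1
    X <- sweep(X, 2, scales, "/")
  }
  colnames(X) <- mset$exposure_ids
  structure(
    list(y = y, X = X, variant_ids = mset$data$variant_id,
         trait_ids = mset$exposure_ids,
         correlation = if (nrow(X) > 1) cor(X) else diag(K),
         scales = scales),
    class = "bma_input")
}

#' Prune near-duplicate risk factors
#'
#' Multivariable methods cannot separate traits whose instrument associations
#' are (near-)perfectly correlated. While any predictor pair has absolute
#' correlation at or above `r_max`, one member of the worst pair is removed
#' at random (seeded, so reproducible); removals are logged.
#'
#' @param input A [bma_input()].
#' @param r_max Correlation threshold (default 0.99).
#' @param seed Seed for the random choice.
#' @return The pruned `bma_input`, with a `removed` attribute.
#' @export
prune_correlated <- function(input, r_max = 0.99, seed = 1L) {
  withr::local_seed(seed)
  X <- input$X
  removed <- character(0)
  repeat {
    if (ncol(X) < 2) break
    cors <- abs(cor(X))
    diag(cors) <- 0
    if (max(cors) < r_max) break
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    drop_k <- unname(worst[sample.int(2, 1)])
    removed <- c(removed, colnames(X)[drop_k])
    X <- X[, -drop_k, drop = FALSE]
  }
  out <- input
  out$X <- X
  out$trait_ids <- colnames(X)
  out$correlation <- if (nrow(X) > 1 && ncol(X) > 1) cor(X)
                     else diag(ncol(X))
  out$scales <- input$scales[match(colnames(X), input$trait_ids)]
  attr(out, "removed") <- removed
  out
}

# Precompute Gram quantities for fast repeated model scoring.
bma_precompute <- function(input, prior_var) {
  list(
    A = crossprod(input$X),          # X'X
    b = drop(crossprod(input$X, input$y)),
    yy = sum(input$y^2),
    J = length(input$y),
    K = ncol(input$X),
    v = prior_var
  )
}

# Closed-form log marginal likelihood and posterior mean for a model subset S
# under the conjugate Gaussian linear model: effects ~ N(0, v I), unit
# residual variance.
bma_score_subset <- function(pre, S, b = pre$b) {
  J <- pre$J
  if (length(S) == 0) {
    return(list(logml = -J / 2 * log(2 * pi) - 0.5 * pre$yy,
                theta = numeric(0)))
  }
  A_S <- pre$A[S, S, drop = FALSE]
  b_S <- b[S]
  C <- A_S + diag(length(S)) / pre$v
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    abort("singular design for model subset", class = "mrscreen_degenerate")
  }
  z <- backsolve(ch, forwardsolve(t(ch), b_S))
  quad <- sum(b_S * z)
  logdet <- length(S) * log(pre$v) + 2 * sum(log(diag(ch)))
  list(
    logml = -J / 2 * log(2 * pi) - 0.5 * logdet - 0.5 * (pre$yy - quad),
    theta = z
  )
}

#' Score one candidate model
#'
#' Closed-form log marginal likelihood and shrinkage estimate for the model
#' containing the traits in `S`, under the conjugate Gaussian linear model
#' with effect prior `N(0, prior_var I)` and unit residual variance; the
#' model prior is `prior_p^|S| (1 - prior_p)^(K - |S|)`.
#'
#' @param input A [bma_input()].
#' @param S Integer or character indices of the included traits.
#' @param prior_p Prior inclusion probability per trait (default 0.1).
#' @param prior_var Prior variance of each included effect (default 0.25).
#' @return A list: `logml`, `log_prior`, `theta` (named posterior-mean
#'   effects on the standardised scale).
#' @export
model_posterior <- function(input, S, prior_p = 0.1, prior_var = 0.25) {
  if (is.character(S)) S <- match(S, input$trait_ids)
  stopifnot(length(S) >= 1, all(is.finite(S)))
  if (length(input$y) <= length(S)) {
    abort("model has as many traits as instruments",
          class = "mrscreen_degenerate")
  }
  pre <- bma_precompute(input, prior_var)
  sc <- bma_score_subset(pre, sort(unique(S)))
  K <- pre$K
  list(
    logml = sc$logml,
    log_prior = length(S) * log(prior_p) + (K - length(S)) * log(1 - prior_p),
    theta = setNames(sc$theta, input$trait_ids[sort(unique(S))])
  )
}

subset_key <- function(S) {
  if (length(S) == 0) "empty" else paste(sort(S), collapse = ",")
}
key_to_subset <- function(key) {
  if (key == "empty") integer(0) else as.integer(strsplit(key, ",")[[1]])
}

# Score all 2^K subsets (including the empty model). Returns keys, log
# posterior scores and theta list.
bma_enumerate <- function(pre, prior_p) {
  K <- pre$K
  n_models <- 2^K
  keys <- character(n_models)
  logpost <- numeric(n_models)
  thetas <- vector("list", n_models)
  sizes <- integer(n_models)
  for (i in seq_len(n_models)) {
    S <- which(bitwAnd(i - 1, bitwShiftL(1, seq_len(K) - 1)) > 0)
    sc <- bma_score_subset(pre, S)
    keys[i] <- subset_key(S)
    sizes[i] <- length(S)
    logpost[i] <- sc$logml + length(S) * log(prior_p) +
      (K - length(S)) * log(1 - prior_p)
    thetas[[i]] <- sc$theta
  }
  list(keys = keys, logpost = logpost, thetas = thetas, sizes = sizes)
}

normalise_cache <- function(keys, logpost, thetas, K) {
  w <- exp(logpost - max(logpost))
  post <- w / sum(w)
  mip <- numeric(K)
  mace <- numeric(K)
  for (i in seq_along(keys)) {
    S <- key_to_subset(keys[i])
    if (length(S) == 0) next
    mip[S] <- mip[S] + post[i]
    mace[S] <- mace[S] + post[i] * thetas[[i]]
  }
  list(post = post, mip = mip, mace = mace)
}

#' Stochastic shotgun search over risk-factor models
#'
#' Explores the model space by add/delete/swap proposals accepted by
#' posterior ratio (Metropolis), caching every distinct model scored; the
#' marginal inclusion probability (MIP) of each trait and the model-averaged
#' causal estimate (MACE) are computed by normalising posterior mass over the
#' cache. For K <= 12 an exhaustive enumeration mode is available
#' (`exhaustive = TRUE`) and the stochastic search agrees with it to within
#' 0.01 per-trait MIP on identifiable designs.
#'
#' @param input A [bma_input()] with K >= 2 traits.
#' @param n_iter Search iterations (default 10000).
#' @param prior_p,prior_var Model and effect priors.
#' @param seed Search seed.
#' @param exhaustive Enumerate all 2^K models instead of searching.
#' @return A `bma_search` list: `models` (tibble: `model`, `size`,
#'   `posterior_prob`, `logml`), `mip` and `mace` (named per trait),
#'   `n_models_visited`, `n_iter`, `seed`.
#' @export
stochastic_search <- function(input, n_iter = 10000, prior_p = 0.1,
                              prior_var = 0.25, seed = 1L,
                              exhaustive = FALSE) {
  K <- ncol(input$X)
  stopifnot(K >= 2)
  pre <- bma_precompute(input, prior_var)
  if (exhaustive) {
    if (K > 12) abort("exhaustive enumeration limited to K <= 12",
                      class = "mrscreen_input")
    en <- bma_enumerate(pre, prior_p)
    keys <- en$keys; logpost <- en$logpost; thetas <- en$thetas
  } else {
    withr::local_seed(seed)
    cache_lp <- new.env(parent = emptyenv())
    cache_th <- new.env(parent = emptyenv())
    score <- function(S) {
      key <- subset_key(S)
      if (is.null(cache_lp[[key]])) {
        sc <- bma_score_subset(pre, S)
        cache_lp[[key]] <- sc$logml + length(S) * log(prior_p) +
          (K - length(S)) * log(1 - prior_p)
        cache_th[[key]] <- sc$theta
      }
      cache_lp[[key]]
    }
    current <- sample.int(K, 1)
    lp_cur <- score(current)
    for (it in seq_len(n_iter)) {
      move <- sample(c("add", "delete", "swap"), 1)
      prop <- current
      if (move == "add" && length(current) < K) {
        prop <- c(current, sample(setdiff(seq_len(K), current), 1))
      } else if (move == "delete" && length(current) > 0) {
        prop <- setdiff(current, current[sample.int(length(current), 1)])
      } else if (move == "swap" && length(current) > 0 &&
                 length(current) < K) {
        out_k <- current[sample.int(length(current), 1)]
        in_k <- sample(setdiff(seq_len(K), current), 1)
        prop <- c(setdiff(current, out_k), in_k)
      }
      lp_prop <- score(prop)
      if (log(runif(1)) < lp_prop - lp_cur) {
        current <- prop
        lp_cur <- lp_prop
      }
    }
    keys <- ls(cache_lp)
    logpost <- vapply(keys, function(k) cache_lp[[k]], numeric(1))
    thetas <- lapply(keys, function(k) cache_th[[k]])
  }
  nc <- normalise_cache(keys, logpost, thetas, K)
  ord <- order(-nc$post)
  structure(
    list(
      models = tibble(model = keys[ord], size = lengths(lapply(keys[ord],
                                                               key_to_subset)),
                      posterior_prob = nc$post[ord], logpost = logpost[ord]),
      mip = setNames(nc$mip, input$trait_ids),
      mace = setNames(nc$mace, input$trait_ids),
      thetas = setNames(thetas, keys),
      n_models_visited = length(keys),
      n_iter = if (exhaustive) NA_integer_ else n_iter,
      seed = seed,
      prior_p = prior_p, prior_var = prior_var,
      exhaustive = exhaustive
    ),
    class = "bma_search")
}

#' Per-variant influence diagnostics for the top MR-BMA models
#'
#' For each top-posterior model: the per-variant contribution to the model's
#' heterogeneity statistic, `q_j = (y_j - x_j' theta_S)^2` (the weighted
#' squared difference between observed and predicted association), and
#' Cook's distance from the corresponding least-squares fit. A variant is
#' flagged when it exceeds either rule in any top model; the range of each
#' statistic across models is reported.
#'
#' @param input A [bma_input()].
#' @param search A `bma_search` result.
#' @param n_top Number of top models to inspect (default 10).
#' @param cooks_rule Cook's distance threshold; default is the median of an
#'   F(|S|, J - |S|) reference distribution per model.
#' @param q_rule Q-contribution threshold; default is the chi-squared(1)
#'   upper point at 0.05 / J (Bonferroni-style).
#' @param prior_var Effect prior variance used for the model fits.
#' @return A tibble per variant: `variant_id`, `cooks_min`, `cooks_max`,
#'   `q_min`, `q_max`, `flagged`.
#' @export
diagnose_outliers <- function(input, search, n_top = 10, cooks_rule = NULL,
                              q_rule = NULL, prior_var = 0.25) {
  J <- length(input$y)
  top <- head(search$models$model[search$models$size > 0], n_top)
  if (length(top) == 0) {
    return(tibble(variant_id = input$variant_ids, cooks_min = NA_real_,
                  cooks_max = NA_real_, q_min = NA_real_, q_max = NA_real_,
                  flagged = FALSE))
  }
  q_rule <- q_rule %||% qchisq(1 - 0.05 / J, df = 1)
  cooks <- matrix(NA_real_, nrow = J, ncol = length(top))
  qs <- matrix(NA_real_, nrow = J, ncol = length(top))
  flagged <- rep(FALSE, J)
  pre <- bma_precompute(input, prior_var)
  for (i in seq_along(top)) {
    S <- key_to_subset(top[i])
    sc <- bma_score_subset(pre, S)
    Xs <- input$X[, S, drop = FALSE]
    resid <- input$y - drop(Xs %*% sc$theta)
    qs[, i] <- resid^2
    fit <- lm(input$y ~ Xs - 1)
    cooks[, i] <- cooks.distance(fit)
    rule_i <- cooks_rule %||% qf(0.5, length(S), J - length(S))
    flagged <- flagged | (qs[, i] > q_rule) |
      (is.finite(cooks[, i]) & cooks[, i] > rule_i)
  }
  tibble(
    variant_id = input$variant_ids,
    cooks_min = apply(cooks, 1, min, na.rm = TRUE),
    cooks_max = apply(cooks, 1, max, na.rm = TRUE),
    q_min = apply(qs, 1, min), q_max = apply(qs, 1, max),
    flagged = flagged
  )
}

# Exhaustive (or search-based) MIPs for permuted responses; vectorised over
# permutations when enumeration is possible.
bma_permutation_mips <- function(input, n_perm, prior_p, prior_var, seed,
                                 n_iter) {
  K <- ncol(input$X)
  J <- length(input$y)
  withr::local_seed(seed)
  perms <- replicate(n_perm, sample.int(J))
  if (K <= 12) {
    pre <- bma_precompute(input, prior_var)
    Z <- crossprod(input$X, matrix(input$y[perms], nrow = J))  # K x n_perm
    n_models <- 2^K
    logml <- matrix(0, nrow = n_models, ncol = n_perm)
    membership <- matrix(FALSE, nrow = n_models, ncol = K)
    logprior <- numeric(n_models)
    const <- -J / 2 * log(2 * pi) - 0.5 * pre$yy
    for (i in seq_len(n_models)) {
      S <- which(bitwAnd(i - 1, bitwShiftL(1, seq_len(K) - 1)) > 0)
      membership[i, S] <- TRUE
      logprior[i] <- length(S) * log(prior_p) +
        (K - length(S)) * log(1 - prior_p)
      if (length(S) == 0) {
        logml[i, ] <- const
        next
      }
      C <- pre$A[S, S, drop = FALSE] + diag(length(S)) / prior_var
      ch <- chol(C)
      Zs <- forwardsolve(t(ch), Z[S, , drop = FALSE])
      quad <- colSums(Zs^2)
      logdet <- length(S) * log(prior_var) + 2 * sum(log(diag(ch)))
      logml[i, ] <- const - 0.5 * logdet + 0.5 * quad
    }
    lp <- logml + logprior
    lp <- sweep(lp, 2, apply(lp, 2, max))
    w <- exp(lp)
    post <- sweep(w, 2, colSums(w), "/")
    t(crossprod(post, membership))  # K x n_perm matrix of MIPs
  } else {
    vapply(seq_len(n_perm), function(p) {
      inp <- input
      inp$y <- input$y[perms[, p]]
      stochastic_search(inp, n_iter = n_iter, prior_p = prior_p,
                        prior_var = prior_var,
                        seed = child_seed(seed, p))$mip
    }, numeric(K))
  }
}

#' Run the full MR-BMA analysis
#'
#' Prune near-duplicate traits, run the stochastic model search, diagnose
#' outlying instruments in the top models, remove any flagged variants and
#' repeat until no outliers remain; then compute per-trait empirical
#' p-values by permutation (response permuted, design fixed — preserving the
#' predictor correlation structure under the null) with Benjamini-Hochberg
#' FDR across traits.
#'
#' @param input A [bma_input()] with K >= 2 traits and J > 2 instruments.
#' @param n_iter Search iterations (default 10000).
#' @param n_perm Permutations for empirical p-values (default 100000;
#'   reduce for test-scale runs).
#' @param prior_p,prior_var Priors (defaults 0.1 and 0.25).
#' @param r_max Correlation pruning threshold (default 0.99).
#' @param seed Seed for pruning, search and permutations.
#' @param exhaustive Use exhaustive enumeration instead of the stochastic
#'   search (K <= 12).
#' @param max_outlier_rounds Safety cap on outlier-removal iterations.
#' @return A `bma_result` list: `traits` (tibble ranked by MIP: `rank`,
#'   `trait_id`, `mip`, `mace`, `empirical_p`, `fdr_p`), `models`,
#'   `outliers_removed`, `search`, `pruned_traits`.
#' @export
run_bma <- function(input, n_iter = 10000, n_perm = 100000, prior_p = 0.1,
                    prior_var = 0.25, r_max = 0.99, seed = 1L,
                    exhaustive = FALSE, max_outlier_rounds = 10) {
  stopifnot(ncol(input$X) >= 2, length(input$y) > 2)
  input <- prune_correlated(input, r_max = r_max, seed = seed)
  pruned <- attr(input, "removed")
  outliers <- list()
  search <- NULL
  for (round in seq_len(max_outlier_rounds)) {
    search <- stochastic_search(input, n_iter = n_iter, prior_p = prior_p,
                                prior_var = prior_var,
                                seed = child_seed(seed, round),
                                exhaustive = exhaustive)
    diag_tab <- diagnose_outliers(input, search, prior_var = prior_var)
    flagged <- diag_tab$variant_id[diag_tab$flagged]
    if (length(flagged) == 0) break
    if (length(flagged) >= length(input$y) - ncol(input$X)) {
      abort("outlier removal left too few instruments for analysis",
            class = "mrscreen_degenerate")
    }
    outliers[[round]] <- diag_tab[diag_tab$flagged, ]
    keep <- !(input$variant_ids %in% flagged)
    input$y <- input$y[keep]
    input$X <- input$X[keep, , drop = FALSE]
    input$variant_ids <- input$variant_ids[keep]
  }
  K <- ncol(input$X)
  mips <- bma_permutation_mips(input, n_perm, prior_p, prior_var,
                               seed = child_seed(seed, 9999),
                               n_iter = n_iter)
  obs <- search$mip
  emp_p <- vapply(seq_len(K), function(k) {
    (1 + sum(mips[k, ] >= obs[k])) / (n_perm + 1)
  }, numeric(1))
  traits <- tibble(
    trait_id = input$trait_ids,
    mip = unname(obs),
    mace = unname(search$mace),
    empirical_p = emp_p,
    fdr_p = p.adjust(emp_p, method = "BH")
  )
  traits <- traits[order(-traits$mip, traits$trait_id), ]
  traits$rank <- seq_len(nrow(traits))
  traits <- traits[c("rank", "trait_id", "mip", "mace", "empirical_p",
                     "fdr_p")]
  structure(
    list(traits = traits, models = search$models,
         outliers_removed = if (length(outliers)) bind_rows(outliers)
                            else tibble(variant_id = character()),
         search = search, pruned_traits = pruned,
         n_perm = n_perm, seed = seed),
    class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf(
    "<bma_result> %d trait(s), %d model(s) cached, %d outlier(s) removed\n",
    nrow(x$traits), nrow(x$models), nrow(x$outliers_removed)))
  print(x$traits)
  invisible(x)
}
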
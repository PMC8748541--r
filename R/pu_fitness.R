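#' Build a binary feature matrix from called substitutions
#'
#' Observations are reads (or sampled variants): the unlabeled input pool
#' and the positive sorted pool. Each retained substitution becomes one
#' binary indicator column. Observations with identical indicator patterns
#' and pool membership are collapsed with multiplicity weights, which keeps
#' the likelihood identical while making optimization cheap at deep
#' sequencing depths.
#'
#' @param input_subs List of character vectors: substitution keys per
#'   input-pool observation.
#' @param sorted_subs Same for the sorted pool.
#' @param min_mutation_count Minimum total occurrences (both pools) for a
#'   substitution to become a feature (default 10).
#' @return A `pu_features` object: `X` (unique-pattern binary matrix),
#'   `z` (1 = sorted), `w` (pattern multiplicities), `n_P`, `n_U`, `keys`,
#'   and per-key occurrence counts `n_input`, `n_sorted`.
#' @export
feature_matrix <- function(input_subs, sorted_subs, min_mutation_count = 10) {
  n_U <- length(input_subs)
  n_P <- length(sorted_subs)
  if (n_U == 0L || n_P == 0L) stop("both pools must be non-empty")
  all_subs <- c(input_subs, sorted_subs)
  z_obs <- rep(c(0L, 1L), c(n_U, n_P))

  flat <- unlist(all_subs, use.names = FALSE)
  obs <- rep.int(seq_along(all_subs), lengths(all_subs))
  cnt <- table(flat)
  keys <- names(cnt)[cnt >= min_mutation_count]
  if (length(keys) == 0L)
    stop("no substitution observed at least ", min_mutation_count, " times")
  parsed <- parse_sub_key(keys)
  keys <- keys[order(parsed$position, parsed$alt)]

  keep <- flat %in% keys
  flat <- flat[keep]
  obs <- obs[keep]
  n_input_key <- n_sorted_key <- stats::setNames(integer(length(keys)), keys)
  ti <- table(flat[z_obs[obs] == 0L])
  ts <- table(flat[z_obs[obs] == 1L])
  n_input_key[names(ti)] <- as.integer(ti)
  n_sorted_key[names(ts)] <- as.integer(ts)

  # collapse identical (pattern, pool) observations
  patt <- character(length(all_subs))
  if (length(flat) > 0L) {
    o <- order(obs, match(flat, keys))
    by_obs <- split(flat[o], obs[o])
    patt[as.integer(names(by_obs))] <-
      vapply(by_obs, paste, "", collapse = ";")
  }
  grp <- paste0(z_obs, "|", patt)
  first <- !duplicated(grp)
  w <- as.integer(table(factor(grp, levels = grp[first])))
  u_patt <- patt[first]
  u_z <- z_obs[first]

  X <- matrix(0, nrow = length(u_patt), ncol = length(keys),
              dimnames = list(NULL, keys))
  hits <- strsplit(u_patt, ";", fixed = TRUE)
  row_id <- rep.int(seq_along(hits), lengths(hits))
  col_id <- match(unlist(hits, use.names = FALSE), keys)
  X[cbind(row_id, col_id)] <- 1

  structure(list(X = X, z = u_z, w = w, n_P = n_P, n_U = n_U,
                 keys = keys, n_input = n_input_key, n_sorted = n_sorted_key),
            class = "pu_features")
}

#' @export
print.pu_features <- function(x, ...) {
  cat(sprintf(
    "<pu_features> %d features; %d sorted + %d input observations (%d unique patterns)\n",
    length(x$keys), x$n_P, x$n_U, nrow(x$X)))
  invisible(x)
}

#' Positive-unlabeled case-control negative log-likelihood
#'
#' The sorted pool is a sample of positives; the input pool is an unlabeled
#' sample with known positive prevalence `prior_pi`. Under case-control
#' sampling, the probability that an observation with activity probability
#' `sigma_i = plogis(beta0 + x_i' beta)` came from the sorted pool is
#' `q_i = n_P sigma_i / (n_P sigma_i + n_U prior_pi)`, and the objective is
#' the Bernoulli negative log-likelihood of the pool indicators `z` under
#' `q`, plus an optional L2 penalty on the slopes (not the intercept).
#' The gradient is exact.
#'
#' @param beta0 Intercept, log-odds units.
#' @param beta Numeric vector of slopes, one per feature.
#' @param features A [feature_matrix()] result.
#' @param prior_pi Fraction of the input pool that is truly active, (0, 1).
#' @param l2_penalty Ridge penalty on slopes (default 0).
#' @return List with `objective` and `gradient` (length 1 + p; intercept
#'   first).
#' @export
pu_negative_log_likelihood <- function(beta0, beta, features, prior_pi,
                                       l2_penalty = 0) {
  if (!(prior_pi > 0 && prior_pi < 1)) stop("prior_pi must be in (0,1)")
  stopifnot(length(beta) == ncol(features$X))
  eta <- drop(beta0 + features$X %*% beta)
  sigma <- stats::plogis(eta)
  a <- features$n_P
  b <- features$n_U * prior_pi
  q <- a * sigma / (a * sigma + b)
  eps <- 1e-12
  if (any(q < eps | q > 1 - eps))
    warning("pool-membership probabilities clamped away from 0/1")
  q <- pmin(pmax(q, eps), 1 - eps)
  z <- features$z
  w <- features$w
  objective <- -sum(w * (z * log(q) + (1 - z) * log(1 - q))) +
    l2_penalty / 2 * sum(beta^2)
  g_eta <- -w * (1 - sigma) * (z - q)
  gradient <- c(sum(g_eta), drop(crossprod(features$X, g_eta)) + l2_penalty * beta)
  list(objective = objective, gradient = gradient)
}

#' Fit per-substitution fitness coefficients by PU logistic regression
#'
#' Minimizes [pu_negative_log_likelihood()] by L-BFGS-B with the analytic
#' gradient. Features observed in only one pool are separable; their slopes
#' are box-constrained to `[-cap, cap]` and flagged with a warning.
#' Convergence is declared when the optimizer reports success at relative
#' objective tolerance `tol`; otherwise the table is returned with the
#' `converged` flag unset.
#'
#' @param features A [feature_matrix()] result.
#' @param prior_pi Known active fraction of the input pool.
#' @param l2_penalty Ridge penalty on slopes (default 1e-4).
#' @param tol Relative objective-change tolerance (default 1e-8).
#' @param max_iter Maximum iterations (default 500).
#' @param seed Integer seed (fit is deterministic; recorded in metadata).
#' @param cap Slope bound for separable features (default 10).
#' @param compute_se If TRUE (default), standard errors from the inverse
#'   observed information at the optimum.
#' @return A `coef_table`: data frame with `key`, `ref`, `position`, `alt`,
#'   `beta`, `se`, `n_input`, `n_sorted`; attributes `beta0`, `prior_pi`,
#'   `l2_penalty`, `converged`, `iterations`, `objective`, `method`.
#' @export
fit_pu_logistic <- function(features, prior_pi, l2_penalty = 1e-4,
                            tol = 1e-8, max_iter = 500L, seed = 1L,
                            cap = 10, compute_se = TRUE) {
  stopifnot(inherits(features, "pu_features"))
  if (!(prior_pi > 0 && prior_pi < 1)) stop("prior_pi must be in (0,1)")
  set.seed(seed)
  p <- length(features$keys)
  separable <- features$n_input == 0L | features$n_sorted == 0L
  if (any(separable))
    warning(sum(separable), " separable feature(s) observed in only one ",
            "pool; slopes capped at +/-", cap)

  fn <- function(par) suppressWarnings(
    pu_negative_log_likelihood(par[1L], par[-1L], features, prior_pi,
                               l2_penalty)$objective)
  gr <- function(par) suppressWarnings(
    pu_negative_log_likelihood(par[1L], par[-1L], features, prior_pi,
                               l2_penalty)$gradient)

  lower <- c(-Inf, ifelse(separable, -cap, -Inf))
  upper <- c(Inf, ifelse(separable, cap, Inf))
  par0 <- c(stats::qlogis(prior_pi), rep(0, p))
  iterations <- 0L
  res <- NULL
  # warm-restart L-BFGS-B until it reports the relative-reduction stop or
  # the iteration budget is exhausted
  for (round in 1:5) {
    res <- stats::optim(if (is.null(res)) par0 else res$par, fn, gr,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = max_iter,
                                       factr = tol / .Machine$double.eps))
    iterations <- iterations + unname(res$counts[1L])
    if (res$convergence == 0L || iterations >= max_iter * 5L) break
  }
  converged <- res$convergence == 0L

  se <- rep(NA_real_, p)
  if (compute_se && converged) {
    se <- tryCatch({
      H <- stats::optimHess(res$par, fn, gr)
      v <- diag(solve(H))
      ifelse(v[-1L] > 0, sqrt(v[-1L]), NA_real_)
    }, error = function(e) rep(NA_real_, p))
  }

  parsed <- parse_sub_key(features$keys)
  out <- data.frame(
    key = features$keys, ref = parsed$ref, position = parsed$position,
    alt = parsed$alt, beta = res$par[-1L], se = se,
    n_input = as.integer(features$n_input),
    n_sorted = as.integer(features$n_sorted)
  )
  rownames(out) <- NULL
  attr(out, "beta0") <- res$par[1L]
  attr(out, "prior_pi") <- prior_pi
  attr(out, "l2_penalty") <- l2_penalty
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "objective") <- res$value
  attr(out, "method") <- "pu_logistic"
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("coef_table", "data.frame")
  out
}

#' Naive log-enrichment baseline
#'
#' Per substitution, the log-ratio of pseudocounted sorted and input
#' frequencies: `log((c_s + a)/(N_s + a)) - log((c_i + a)/(N_i + a))`.
#' A diagnostic baseline for the PU fit, not a calibrated effect size.
#'
#' @param table A `count_table` (after thresholding).
#' @param pseudocount Additive pseudocount `a` > 0 (default 0.5).
#' @return A `coef_table` with `method = "naive_log_enrichment"`.
#' @export
naive_log_enrichment <- function(table, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  a <- pseudocount
  Ni <- attr(table, "n_input")
  Ns <- attr(table, "n_sorted")
  beta <- log((table$count_sorted + a) / (Ns + a)) -
    log((table$count_input + a) / (Ni + a))
  out <- data.frame(key = table$key, ref = table$ref,
                    position = table$position, alt = table$alt,
                    beta = beta, se = NA_real_,
                    n_input = table$count_input,
                    n_sorted = table$count_sorted)
  rownames(out) <- NULL
  attr(out, "method") <- "naive_log_enrichment"
  attr(out, "pseudocount") <- a
  class(out) <- c("coef_table", "data.frame")
  out
}

#' @export
print.coef_table <- function(x, ...) {
  cat(sprintf("<coef_table> %d substitutions (%s)\n",
              nrow(x), attr(x, "method")))
  if (!is.null(attr(x, "beta0")))
    cat(sprintf("  beta0 = %.3f, converged: %s\n",
                attr(x, "beta0"), attr(x, "converged")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Cross-replicate coefficient concordance and outlier exclusion
#'
#' Pearson correlations of coefficients over the substitutions shared by all
#' replicates. Replicates are excluded iteratively: while at least 3
#' replicates remain, the replicate with the lowest mean pairwise
#' correlation is dropped if that mean is below `exclusion_threshold`, and
#' the means are recomputed (so one discordant replicate cannot drag its
#' concordant partners below the cutoff). With only 2 replicates no
#' exclusion is possible.
#'
#' @param tables List of `coef_table`s, one per replicate (named or not).
#' @param exclusion_threshold Mean-correlation cutoff (default 0.5).
#' @return List with `correlations` (matrix), `shared_substitutions`,
#'   and `excluded` (replicate names).
#' @export
replicate_concordance <- function(tables, exclusion_threshold = 0.5) {
  if (length(tables) < 2L) stop("need at least 2 replicate tables")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("rep", seq_along(tables))
  shared <- Reduce(intersect, lapply(tables, function(t) t$key))
  if (length(shared) < 20L)
    stop("replicates share only ", length(shared),
         " substitutions (>= 20 required)")
  mat <- vapply(tables, function(t) t$beta[match(shared, t$key)],
                numeric(length(shared)))
  cors <- stats::cor(mat, method = "pearson")
  excluded <- character(0)
  active <- names(tables)
  while (length(active) >= 3L) {
    sub <- cors[active, active, drop = FALSE]
    mean_pair <- (rowSums(sub) - 1) / (length(active) - 1)
    worst <- which.min(mean_pair)
    if (mean_pair[worst] >= exclusion_threshold) break
    excluded <- c(excluded, active[worst])
    active <- active[-worst]
  }
  list(correlations = cors, shared_substitutions = shared,
       excluded = excluded)
}

#' Combine replicate coefficient tables
#'
#' Count-weighted mean of per-substitution coefficients across retained
#' replicates; the weight of a replicate's estimate is its total observation
#' count for that substitution.
#'
#' @param tables Named list of `coef_table`s.
#' @param excluded Replicate names to drop (e.g. from
#'   [replicate_concordance()]).
#' @return A combined `coef_table` (counts summed over retained replicates).
#' @export
combine_replicates <- function(tables, excluded = character(0)) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("rep", seq_along(tables))
  keep <- setdiff(names(tables), excluded)
  if (length(keep) == 0L) stop("all replicates excluded")
  tabs <- tables[keep]
  df <- do.call(rbind, lapply(tabs, function(t)
    data.frame(key = t$key, beta = t$beta,
               n = t$n_input + t$n_sorted,
               n_input = t$n_input, n_sorted = t$n_sorted)))
  wsum <- rowsum(df$beta * df$n, df$key)
  w <- rowsum(df$n, df$key)
  ni <- rowsum(df$n_input, df$key)
  ns <- rowsum(df$n_sorted, df$key)
  keys <- rownames(wsum)
  parsed <- parse_sub_key(keys)
  out <- data.frame(key = keys, ref = parsed$ref, position = parsed$position,
                    alt = parsed$alt, beta = wsum[, 1L] / w[, 1L],
                    se = NA_real_, n_input = ni[, 1L], n_sorted = ns[, 1L])
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "combined"
  attr(out, "replicates") <- keep
  attr(out, "beta0") <- mean(vapply(tabs, function(t)
    attr(t, "beta0") %||% NA_real_, numeric(1L)), na.rm = TRUE)
  class(out) <- c("coef_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coefficient table as TSV with a JSON metadata sidecar
#'
#' @param table A `coef_table`.
#' @param path Output TSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(method = attr(table, "method"), beta0 = attr(table, "beta0"),
               prior_pi = attr(table, "prior_pi"),
               l2_penalty = attr(table, "l2_penalty"),
               converged = attr(table, "converged"),
               iterations = attr(table, "iterations"),
               objective = attr(table, "objective"),
               seed = attr(table, "seed"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))],
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
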
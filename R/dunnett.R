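#' Dunnett many-to-one comparison of per-variant counts against a control
#'
#' Classical Dunnett procedure: each treatment group is compared with the
#' single control using pooled-variance t statistics, and the family-wise
#' adjusted p-value of treatment *i* is \eqn{P(\max_j |T_j| \ge |t_i|)}
#' under the equicorrelated multivariate-t reference distribution with
#' correlations \eqn{\rho_{ij} = \lambda_i \lambda_j},
#' \eqn{\lambda_i = \sqrt{n_i / (n_i + n_0)}}. The reference distribution is
#' evaluated by seeded Monte Carlo, so results are exactly reproducible
#' given `(seed, mc_draws)`; the Monte-Carlo standard error of each p-value
#' is reported. Tests are two-sided. Adjusted p-values are floored at the
#' unadjusted two-sample p so the adjustment is never anti-conservative.
#'
#' @param control Numeric vector of control observations (length >= 2).
#' @param treatments Named list of numeric vectors (each length >= 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for the Monte-Carlo draws (required).
#' @param mc_draws Number of Monte-Carlo draws (default 1e5).
#' @return Object of class `gelp_dunnett`; see [tidy.gelp_dunnett()].
#' @examples
#' d <- dunnett_many_to_one(c(44, 51, 38, 49, 45),
#'                          list(mut = c(20, 26, 18, 25, 21)), seed = 1)
#' tidy(d)
#' @export
dunnett_many_to_one <- function(control, treatments, alpha = 0.05,
                                seed, mc_draws = 1e5) {
  if (!is.list(treatments)) treatments <- list(treatments)
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    names(treatments) <- paste0("treatment", seq_along(treatments))
  }
  ns <- c(length(control), lengths(treatments))
  if (any(ns < 2)) abort("every group needs at least 2 observations.")
  means <- c(mean(control), vapply(treatments, mean, 0))
  vars <- c(var(control), vapply(treatments, var, 0))
  dunnett_engine(means, vars, ns, names(treatments), alpha, seed, mc_draws)
}

#' Dunnett test from printed group summaries
#'
#' Re-analysis entry point for published mean/sd/n tables (e.g. reasonable
#' model counts reported as mean ± sd). The per-group `n` is an explicit
#' input because published summaries often omit it; the chosen value is
#' carried into the result so the assumption is never silent.
#'
#' @param control Numeric `c(mean, sd, n)` for the control group.
#' @param treatments Data frame with columns `group`, `mean`, `sd`, `n`.
#' @inheritParams dunnett_many_to_one
#' @return Object of class `gelp_dunnett`.
#' @export
dunnett_from_summary <- function(control, treatments, alpha = 0.05,
                                 seed, mc_draws = 1e5) {
  stopifnot(length(control) == 3, is.data.frame(treatments),
            all(c("group", "mean", "sd", "n") %in% names(treatments)))
  ns <- c(control[3], treatments$n)
  if (any(ns < 2)) abort("every group needs n >= 2.")
  means <- c(control[1], treatments$mean)
  vars <- c(control[2], treatments$sd)^2
  dunnett_engine(means, vars, ns, treatments$group, alpha, seed, mc_draws)
}

#' Dunnett test from a tidy observation table
#'
#' Data-frame-first wrapper around [dunnett_many_to_one()].
#'
#' @param data Data frame with one observation per row.
#' @param value Name of the numeric response column.
#' @param group Name of the group column.
#' @param control Label of the control group within `group`.
#' @inheritParams dunnett_many_to_one
#' @return Object of class `gelp_dunnett`.
#' @export
dunnett_test <- function(data, value, group, control = "native",
                         alpha = 0.05, seed, mc_draws = 1e5) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  g <- as.character(data[[group]])
  if (!control %in% g) abort(paste0("control group '", control, "' not found."))
  ctrl <- data[[value]][g == control]
  trt_levels <- setdiff(unique(g), control)
  if (length(trt_levels) == 0) abort("no treatment variants.")
  trts <- lapply(trt_levels, function(lv) data[[value]][g == lv])
  names(trts) <- trt_levels
  dunnett_many_to_one(ctrl, trts, alpha = alpha, seed = seed,
                      mc_draws = mc_draws)
}

# core computation from sufficient statistics; first group is the control
dunnett_engine <- function(means, vars, ns, trt_names, alpha, seed, mc_draws) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  means <- unname(means); vars <- unname(vars); ns <- unname(ns)
  k <- length(means) - 1
  df <- sum(ns - 1)
  s2 <- sum((ns - 1) * vars) / df
  diff <- means[-1] - means[1]
  se <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  if (s2 <= 0) {
    if (all(diff == 0)) {
      warn("zero pooled variance with equal means; p = 1.")
      tstat <- rep(0, k); p_adj <- rep(1, k); p_un <- rep(1, k)
    } else {
      warn("zero pooled variance with unequal means; p = 0.")
      tstat <- ifelse(diff == 0, 0, sign(diff) * Inf)
      p_adj <- ifelse(diff == 0, 1, 0)
      p_un <- p_adj
    }
    mc_se <- rep(0, k)
  } else {
    tstat <- diff / se
    p_un <- 2 * pt(-abs(tstat), df)
    lambda <- sqrt(ns[-1] / (ns[-1] + ns[1]))
    maxT <- with_preserved_seed(seed, {
      z0 <- rnorm(mc_draws)
      w <- sqrt(rchisq(mc_draws, df) / df)
      m <- vapply(seq_len(k), function(j) {
        abs(lambda[j] * z0 + sqrt(1 - lambda[j]^2) * rnorm(mc_draws)) / w
      }, numeric(mc_draws))
      if (k == 1) as.numeric(m) else do.call(pmax, asplit(m, 2))
    })
    p_mc <- vapply(abs(tstat), function(t0) mean(maxT >= t0), 0)
    mc_se <- sqrt(pmax(p_mc * (1 - p_mc), 1 / mc_draws) / mc_draws)
    p_adj <- pmax(p_mc, p_un)  # never anti-conservative
  }
  table <- tibble::tibble(
    group = trt_names, n = ns[-1], mean = means[-1], diff = diff,
    t = tstat, p_unadj = p_un, p_adj = p_adj, mc_se = mc_se,
    significant = p_adj <= alpha
  )
  structure(list(table = table,
                 control = tibble::tibble(n = ns[1], mean = means[1]),
                 alpha = alpha, df = df, s_pooled = sqrt(max(s2, 0)),
                 seed = seed, mc_draws = mc_draws,
                 method = "monte_carlo"),
            class = "gelp_dunnett")
}

# run code with a temporary RNG state, restoring the caller's stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.gelp_dunnett <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one (two-sided, Monte Carlo %d draws, seed %s)\n",
              x$mc_draws, format(x$seed)))
  cat(sprintf("control: mean %.3f (n = %d); pooled sd %.3f on %d df; alpha %.3g\n",
              x$control$mean, x$control$n, x$s_pooled, x$df, x$alpha))
  print(x$table)
  invisible(x)
}

#' Tidy a Dunnett result
#'
#' @param x A `gelp_dunnett` object.
#' @param ... Unused.
#' @return One row per treatment group: `group`, `n`, `mean`, `diff`, `t`,
#'   `p_unadj`, `p_adj`, `mc_se`, `significant`.
#' @method tidy gelp_dunnett
#' @export
tidy.gelp_dunnett <- function(x, ...) x$table

#' @rdname tidy.gelp_dunnett
#' @return For `glance()`: a one-row tibble of run metadata.
#' @method glance gelp_dunnett
#' @export
glance.gelp_dunnett <- function(x, ...) {
  tibble::tibble(k = nrow(x$table), df = x$df, s_pooled = x$s_pooled,
                 alpha = x$alpha, mc_draws = x$mc_draws, seed = x$seed,
                 n_significant = sum(x$table$significant),
                 method = x$method)
}
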
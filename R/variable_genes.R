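# Highly-variable-gene selection: per-gene coefficient of variation across
# strains, two-component normal decomposition of the CV distribution by EM,
# and a mean-expression floor on the log2 scale.

#' Per-gene coefficient of variation
#'
#' Sample mean, sample sd (n - 1 denominator) and CV = sd / mean computed
#' across strains, pairwise-complete. Genes with fewer than 3 non-missing
#' values are flagged unusable; genes with non-positive mean get a missing
#' CV (with a warning), since the CV is undefined there.
#'
#' @param expr An [expression_matrix()].
#' @return A data frame (`CVProfile`) with columns `gene`, `mean`, `sd`,
#'   `cv`, `n_obs`, `usable`.
#' @export
compute_cv <- function(expr) {
  m <- unclass(expr)
  n_obs <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 1, stats::sd, na.rm = TRUE)
  usable <- n_obs >= 3
  cv <- sd_ / mu
  bad_mean <- usable & !is.na(mu) & mu <= 0
  if (any(bad_mean)) {
    warning(sum(bad_mean), " gene(s) with non-positive mean: CV undefined")
    cv[bad_mean] <- NA_real_
  }
  cv[!usable] <- NA_real_
  data.frame(gene = rownames(m), mean = mu, sd = sd_, cv = cv,
             n_obs = n_obs, usable = usable,
             row.names = NULL, stringsAsFactors = FALSE)
}

gauss_loglik <- function(x, pi1, mu, sigma) {
  sum(log(pi1 * stats::dnorm(x, mu[1], sigma[1]) +
            (1 - pi1) * stats::dnorm(x, mu[2], sigma[2])))
}

#' Fit a two-component normal mixture to CV values by EM
#'
#' Standard two-component Gaussian EM initialized by a median split
#' (values below/above the median seed the two components). Components are
#' relabeled after convergence so component 2 has the larger mean — the
#' "variable" population on the right side of the CV distribution. The EM
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param cvs Numeric vector of CV values (non-finite entries dropped;
#'   at least 10 finite values required).
#' @param seed Seed for jittered restarts on degeneracy.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @return A `MixtureFit` list: `weights`, `means`, `sds` (component 2 =
#'   higher mean), `responsibility` (per input value, probability of the
#'   higher-mean component; NA where the input was non-finite),
#'   `loglik`, `loglik_trace`, `iterations`, `converged`.
#' @export
fit_cv_mixture <- function(cvs, seed = 1L, tol = 1e-8, max_iter = 500L) {
  finite <- is.finite(cvs)
  x <- cvs[finite]
  if (length(x) < 10) stop("need at least 10 finite CV values")
  set.seed(seed)

  run_em <- function(mu, sigma, pi1) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      d1 <- pi1 * stats::dnorm(x, mu[1], sigma[1])
      d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sigma[2])
      tot <- d1 + d2
      if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
      r2 <- d2 / tot
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      if (ll < ll_old - 1e-9)
        stop("EM log-likelihood decreased; numerical failure")
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      # M step
      w2 <- mean(r2)
      if (w2 < 1e-12 || w2 > 1 - 1e-12) return(NULL)
      mu <- c(sum((1 - r2) * x) / sum(1 - r2), sum(r2 * x) / sum(r2))
      sigma <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2),
                      sum(r2 * (x - mu[2])^2) / sum(r2)))
      if (any(sigma < 1e-10)) return(NULL)
      pi1 <- 1 - w2
    }
    list(mu = mu, sigma = sigma, pi1 = pi1, r2 = r2,
         ll = ll_trace[length(ll_trace)], trace = ll_trace,
         iterations = it, converged = converged)
  }

  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) hi <- lo
  init <- list(mu = c(mean(lo), mean(hi)),
               sigma = pmax(c(stats::sd(lo), stats::sd(hi)), 1e-6, na.rm = TRUE),
               pi1 = 0.5)
  init$sigma[is.na(init$sigma)] <- 1e-6
  fit <- run_em(init$mu, init$sigma, init$pi1)
  restarts <- 0L
  while (is.null(fit) && restarts < 5L) {
    restarts <- restarts + 1L
    jmu <- init$mu + stats::rnorm(2, 0, max(stats::sd(x), 1e-3))
    jsig <- pmax(init$sigma * stats::runif(2, 0.5, 2), 1e-4)
    fit <- run_em(jmu, jsig, stats::runif(1, 0.3, 0.7))
  }
  if (is.null(fit))
    stop("mixture fit degenerate after 5 restarts (are the values nearly constant?)")

  # relabel so component 2 has the larger mean
  if (fit$mu[1] > fit$mu[2]) {
    fit$mu <- rev(fit$mu); fit$sigma <- rev(fit$sigma)
    fit$pi1 <- 1 - fit$pi1; fit$r2 <- 1 - fit$r2
  }
  resp <- rep(NA_real_, length(cvs))
  resp[finite] <- fit$r2
  structure(list(weights = c(fit$pi1, 1 - fit$pi1),
                 means = fit$mu, sds = fit$sigma,
                 responsibility = resp,
                 loglik = fit$ll, loglik_trace = fit$trace,
                 iterations = fit$iterations, converged = fit$converged),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(
    "MixtureFit: pi = (%.3f, %.3f), mu = (%.4f, %.4f), sigma = (%.4f, %.4f)\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2], x$sds[1], x$sds[2]))
  cat(sprintf("  loglik %.3f after %d iterations (converged: %s)\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Density-crossing threshold between the two mixture components
#'
#' The CV value between the two component means where the weighted
#' densities are equal; an alternative decision boundary to the
#' responsibility rule.
#'
#' @param fit A `MixtureFit`.
#' @return The crossing point (numeric scalar).
#' @export
mixture_crossing <- function(fit) {
  f <- function(v) fit$weights[2] * stats::dnorm(v, fit$means[2], fit$sds[2]) -
    fit$weights[1] * stats::dnorm(v, fit$means[1], fit$sds[1])
  stats::uniroot(f, lower = fit$means[1], upper = fit$means[2])$root
}

#' Select variable genes
#'
#' A gene is kept when its posterior responsibility for the higher-mean
#' ("variable") CV component exceeds `resp_cutoff` and its mean expression
#' is at least `mean_floor` on the log2 scale (the conventional "average
#' expression value less than 8 removed" step). With `rule =
#' "crossing"` the CV itself is compared against the density-crossing
#' point instead of using responsibilities.
#'
#' @param profile Output of [compute_cv()].
#' @param fit Output of [fit_cv_mixture()] on `profile$cv`.
#' @param mean_floor Log2-scale mean floor (default 8).
#' @param resp_cutoff Responsibility cutoff (default 0.5, strict `>`).
#' @param rule `"responsibility"` (default) or `"crossing"`.
#' @param condition Condition label recorded as provenance.
#' @return A `VariableGeneSet` list: `genes` (selected ids), `table`
#'   (per-gene cv/mean/responsibility/selected), `thresholds`,
#'   `condition`.
#' @export
select_variable_genes <- function(profile, fit, mean_floor = 8,
                                  resp_cutoff = 0.5,
                                  rule = c("responsibility", "crossing"),
                                  condition = NA_character_) {
  rule <- match.arg(rule)
  if (!fit$converged) stop("mixture fit did not converge")
  resp <- fit$responsibility
  variable <- if (rule == "responsibility") {
    !is.na(resp) & resp > resp_cutoff
  } else {
    thr <- mixture_crossing(fit)
    !is.na(profile$cv) & profile$cv > thr
  }
  selected <- variable & !is.na(profile$mean) & profile$mean >= mean_floor
  tab <- data.frame(gene = profile$gene, mean = profile$mean,
                    cv = profile$cv, responsibility = resp,
                    variable = variable, selected = selected,
                    stringsAsFactors = FALSE)
  structure(list(genes = profile$gene[selected], table = tab,
                 thresholds = list(mean_floor = mean_floor,
                                   resp_cutoff = resp_cutoff, rule = rule),
                 condition = condition),
            class = "VariableGeneSet")
}

#' Merge variable-gene sets across conditions
#'
#' Set union with per-condition provenance retained.
#'
#' @param sets List of `VariableGeneSet` objects.
#' @return A merged `VariableGeneSet` whose `provenance` maps each gene to
#'   the conditions that selected it.
#' @export
merge_conditions <- function(sets) {
  if (!length(sets)) stop("need at least one VariableGeneSet")
  genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  prov <- lapply(stats::setNames(genes, genes), function(g)
    unlist(lapply(sets, function(s) if (g %in% s$genes) s$condition else NULL)))
  structure(list(genes = genes, table = NULL,
                 thresholds = sets[[1]]$thresholds,
                 condition = "merged", provenance = prov),
            class = "VariableGeneSet")
}
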
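# Deep mutational scan (DMS) ground-truth processing: per-site scores and
# binarisation into sector / non-sector sites.

#' Per-site DMS scores from per-mutation log enrichments
#'
#' Reduces a long table of per-mutation log enrichment ratios
#' \eqn{\log(r_{mut}/r_{WT})} to one score per site: the minimum (most
#' negative, i.e. most deleterious mutation). Sites without measurements are
#' flagged and excluded.
#'
#' @param dms data.frame with columns `site` and `score` (one row per
#'   measured mutation).
#' @return data.frame with columns `site` and `score`, one row per measured
#'   site, ordered by site.
#' @export
dms_site_scores <- function(dms) {
  if (!all(c("site", "score") %in% names(dms)))
    stop("dms table must have columns 'site' and 'score'")
  dms <- dms[!is.na(dms$score), , drop = FALSE]
  if (!nrow(dms)) stop("no DMS measurements")
  agg <- stats::aggregate(score ~ site, data = dms, FUN = min)
  agg[order(agg$site), ]
}

# ---- 1-D Gaussian mixture machinery (hand-rolled: no mixture package in the
# environment). EM for a 2-component mixture with k-quantile initialization.

fit_gaussian1 <- function(x) {
  mu <- mean(x); sd <- stats::sd(x)
  ll <- sum(stats::dnorm(x, mu, sd, log = TRUE))
  list(k = 1L, mean = mu, sd = sd, loglik = ll,
       bic = -2 * ll + 2 * log(length(x)))
}

em_gaussian2 <- function(x, mu, sd, w, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  sd_floor <- max(stats::sd(x) * 1e-3, 1e-6) # guard against spike components
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    if (any(w < 1e-8)) break
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sd[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    sd[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    sd <- pmax(sd, sd_floor)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  mu <- mu[ord]; sd <- sd[ord]; w <- w[ord]
  ll <- sum(log(w[1] * stats::dnorm(x, mu[1], sd[1]) +
                  w[2] * stats::dnorm(x, mu[2], sd[2])))
  list(k = 2L, mean = mu, sd = sd, weight = w, loglik = ll,
       bic = -2 * ll + 5 * log(n))
}

fit_gaussian2 <- function(x) {
  n <- length(x)
  o <- sort(x)
  half <- floor(n / 2)
  km <- suppressWarnings(stats::kmeans(x, centers = range(x), iter.max = 50))
  grp <- km$cluster == which.min(km$centers)
  starts <- list(
    list(mu = c(mean(o[seq_len(half)]), mean(o[(half + 1):n])),
         sd = rep(stats::sd(x) / 2, 2), w = c(0.5, 0.5)),
    list(mu = sort(as.vector(km$centers)),
         sd = pmax(c(stats::sd(x[grp]), stats::sd(x[!grp])),
                   stats::sd(x) / 10, na.rm = TRUE),
         w = pmax(pmin(c(mean(grp), mean(!grp)), 0.95), 0.05)),
    list(mu = stats::quantile(x, c(0.1, 0.7), names = FALSE),
         sd = rep(stats::sd(x) / 3, 2), w = c(0.2, 0.8)))
  fits <- lapply(starts, function(s)
    tryCatch(em_gaussian2(x, s$mu, s$sd, s$w), error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("mixture fit failed")
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

mixture_density <- function(fit) {
  function(t) fit$weight[1] * stats::dnorm(t, fit$mean[1], fit$sd[1]) +
    fit$weight[2] * stats::dnorm(t, fit$mean[2], fit$sd[2])
}

# KDE modes: local maxima of a kernel density estimate (standard bandwidth
# rule). Peaks without prominence -- minor bumps whose valley to a taller
# neighbor is shallow, or peaks far below the tallest -- are merged away so
# sampling noise does not split one cluster into several modes.
kde_modes <- function(x, min_height = 0.05, min_dip = 0.8) {
  den <- stats::density(x)
  y <- den$y
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= min_height * max(y[i])]
  # merge adjacent maxima separated by a shallow valley
  repeat {
    if (length(i) < 2) break
    merged <- FALSE
    for (k in seq_len(length(i) - 1)) {
      valley <- min(y[i[k]:i[k + 1]])
      if (valley > min_dip * min(y[i[k]], y[i[k + 1]])) {
        drop <- if (y[i[k]] < y[i[k + 1]]) k else k + 1
        i <- i[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  den$x[i]
}

#' Binarise DMS site scores into sector / non-sector
#'
#' Fits either a single Gaussian or a two-component Gaussian mixture to the
#' per-site scores (selected by BIC under `modality = "auto"`, overridable).
#' The binarisation cutoff is the fitted mean for unimodal score
#' distributions and the location of the minimum of the fitted mixture
#' density between the two component means for bimodal ones. When the score
#' distribution shows more than two density peaks, the bimodal fit is
#' restricted to the scores below the midpoint between the second and third
#' most negative peaks (i.e. to the two most negative peaks). The sector is
#' the set of sites with scores below the cutoff.
#'
#' @param scores numeric per-site scores (e.g. from [dms_site_scores()]);
#'   more negative = more deleterious.
#' @param modality `"auto"` (BIC selection), `"unimodal"` or `"bimodal"`.
#' @param min_weight degenerate-fit guard: a mixture component with weight
#'   below this falls back to the unimodal rule with a warning.
#' @return list of class `dms_table`: `scores`, `modality`, `cutoff`,
#'   `labels` (logical, `score < cutoff`), `L_S`, `fit`.
#' @export
binarise_dms <- function(scores, modality = c("auto", "unimodal", "bimodal"),
                         min_weight = 0.01) {
  modality <- match.arg(modality)
  x <- scores[!is.na(scores)]
  if (length(x) < 5) stop("too few scores to binarise")

  fit1 <- fit_gaussian1(x)
  x_fit <- x
  modes <- kde_modes(x)
  if (length(modes) > 2) {
    cutpt <- mean(sort(modes)[2:3])
    x_fit <- x[x <= cutpt]
    if (length(x_fit) < 5) x_fit <- x
  }
  fit2 <- tryCatch(fit_gaussian2(x_fit), error = function(e) NULL)

  use_bimodal <- switch(modality,
    auto = !is.null(fit2) && fit2$bic < fit1$bic,
    unimodal = FALSE,
    bimodal = TRUE)
  if (use_bimodal && (is.null(fit2) || min(fit2$weight) < min_weight)) {
    warning("degenerate mixture fit; falling back to unimodal cutoff")
    use_bimodal <- FALSE
  }

  if (use_bimodal) {
    dens <- mixture_density(fit2)
    opt <- stats::optimize(dens, interval = sort(fit2$mean))
    cutoff <- opt$minimum
    fit <- fit2
    mod <- "bimodal"
  } else {
    cutoff <- fit1$mean
    fit <- fit1
    mod <- "unimodal"
  }
  labels <- scores < cutoff
  structure(list(scores = scores, modality = mod, cutoff = cutoff,
                 labels = labels, L_S = sum(labels, na.rm = TRUE), fit = fit),
            class = "dms_table")
}

#' @export
print.dms_table <- function(x, ...) {
  cat(sprintf("dms_table: %d sites, %s fit, cutoff %.3f, L_S = %d\n",
              length(x$scores), x$modality, x$cutoff, x$L_S))
  invisible(x)
}
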
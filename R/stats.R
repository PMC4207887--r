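# Statistical layer: per-mode summaries, Friedman test with Dunn's post
# hoc across paired conditions, D'Agostino-Pearson normality test, and
# exponential least-squares regression of wasted efforts on the decoupled
# NeuroSync index.

#' Summarise one ventilator mode
#'
#' Runs the full interaction analysis ([neurosync()]) on the trailing
#' analysis window of a recording and returns it as a labelled mode
#' result. A recording failing the EAdi quality gate is refused with a
#' `ns_quality_error` condition carrying the verdict.
#'
#' @param rec A [recording()].
#' @param window_s Analysis window in seconds (default 300).
#' @param mode_label Label for the mode (defaults to the recording's
#'   `meta$mode`).
#' @param ... Passed to [neurosync()].
#' @return A list of class `ns_mode_result` with `mode_label`, `report`
#'   (the `neurosync` object) and `pattern` (its breathing-pattern
#'   medians).
#' @export
summarize_mode <- function(rec, window_s = 300, mode_label = NULL, ...) {
  fit <- neurosync(rec, window_s = window_s, ...)
  structure(list(
    mode_label = mode_label %||% fit$meta$mode %||% "unlabelled",
    report = fit,
    pattern = fit$pattern
  ), class = "ns_mode_result")
}

#' @export
print.ns_mode_result <- function(x, ...) {
  cat("Mode:", x$mode_label, "\n")
  print(x$report)
  invisible(x)
}

friedman_statistic <- function(rank_mat) {
  # rank_mat: subjects x modes, within-subject ranks (ties averaged)
  n <- nrow(rank_mat); k <- ncol(rank_mat)
  Rj <- colSums(rank_mat)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

#' Compare paired conditions with the Friedman test and Dunn's post hoc
#'
#' Nonparametric repeated-measures comparison of a per-subject value
#' across ventilator modes: the Friedman test on within-subject ranks,
#' followed by Dunn's pairwise post hoc comparisons (rank-sum z
#' statistics with Bonferroni-adjusted critical values). Requires
#' complete blocks (every subject measured in every mode) and at least 3
#' subjects. For small designs an exact permutation p-value can be
#' computed by enumerating all within-block rank orderings.
#'
#' @param data A data frame with columns for subject, mode and value.
#' @param value,mode,subject Column names (defaults `"value"`, `"mode"`,
#'   `"subject"`).
#' @param exact Compute the exact permutation p-value by enumeration
#'   (feasible up to ~8 subjects with 3-4 modes).
#' @param alpha Significance level for flagging (default 0.05).
#' @return A list of class `ns_friedman` with `statistic`, `df`,
#'   `p_value`, `p_exact` (if requested), `dunn` (pairwise table), `n`,
#'   `k` and `ranks`.
#' @export
compare_modes <- function(data, value = "value", mode = "mode",
                          subject = "subject", exact = FALSE,
                          alpha = 0.05) {
  df <- as.data.frame(data)
  for (cl in c(value, mode, subject))
    if (!cl %in% names(df))
      stop("column '", cl, "' not found", call. = FALSE)
  modes <- unique(as.character(df[[mode]]))
  subjects <- unique(as.character(df[[subject]]))
  k <- length(modes); n <- length(subjects)
  if (n < 3L)
    stop("at least 3 subjects are required (got ", n, ")", call. = FALSE)
  if (k < 2L) stop("at least 2 modes are required", call. = FALSE)
  mat <- matrix(NA_real_, n, k, dimnames = list(subjects, modes))
  for (r in seq_len(nrow(df)))
    mat[as.character(df[[subject]][r]), as.character(df[[mode]][r])] <-
      df[[value]][r]
  if (anyNA(mat)) {
    bad <- subjects[apply(mat, 1, anyNA)][1L]
    stop("incomplete block: subject '", bad,
         "' is missing a value for at least one mode", call. = FALSE)
  }
  ranks <- t(apply(mat, 1, rank))
  stat <- friedman_statistic(ranks)
  p_chisq <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)

  p_exact <- NA_real_
  if (exact) {
    if (n > 8L || k > 4L)
      stop("exact enumeration is limited to n <= 8 subjects, k <= 4 modes",
           call. = FALSE)
    perm_idx <- permutations_of(k)
    n_perm <- nrow(perm_idx)
    # enumerate all (k!)^n within-block orderings of the observed ranks
    combo <- rep(1L, n)
    total <- n_perm^n
    ge <- 0L
    for (it in seq_len(total)) {
      rm2 <- ranks
      for (b in seq_len(n)) rm2[b, ] <- ranks[b, perm_idx[combo[b], ]]
      if (friedman_statistic(rm2) >= stat - 1e-12) ge <- ge + 1L
      # odometer increment
      b <- 1L
      while (b <= n) {
        combo[b] <- combo[b] + 1L
        if (combo[b] <= n_perm) break
        combo[b] <- 1L; b <- b + 1L
      }
    }
    p_exact <- ge / total
  }

  # Dunn's post hoc on Friedman rank sums
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  se <- sqrt(k * (k + 1) / (6 * n))
  dunn <- data.frame(
    comparison = character(n_comp), z = numeric(n_comp),
    p = numeric(n_comp), p_adj = numeric(n_comp),
    significant = logical(n_comp), stringsAsFactors = FALSE
  )
  mean_ranks <- colMeans(ranks)
  for (j in seq_len(n_comp)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    z <- (mean_ranks[a] - mean_ranks[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    dunn$comparison[j] <- paste(modes[a], "vs", modes[b])
    dunn$z[j] <- z
    dunn$p[j] <- p
    dunn$p_adj[j] <- min(1, p * n_comp)
    dunn$significant[j] <- dunn$p_adj[j] < alpha
  }
  structure(list(statistic = stat, df = k - 1, p_value = p_chisq,
                 p_exact = p_exact, dunn = dunn, n = n, k = k,
                 ranks = ranks, mean_ranks = mean_ranks, alpha = alpha),
            class = "ns_friedman")
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(k)) {
    r <- r + 1L
    row <- integer(k)
    row[pos] <- k
    row[-pos] <- sub[i, ]
    out[r, ] <- row
  }
  out
}

#' @export
print.ns_friedman <- function(x, ...) {
  cat(sprintf("Friedman test: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (is.finite(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g\n", x$p_exact))
  cat(sprintf("  (%d subjects x %d modes)\n", x$n, x$k))
  cat("Dunn's post hoc (Bonferroni-adjusted):\n")
  print(x$dunn, row.names = FALSE, digits = 4)
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected z-transforms of skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) into the omnibus statistic
#' K-squared = z_skew^2 + z_kurt^2, referred to a chi-squared distribution
#' with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x Numeric vector of observations.
#' @return A list of class `ns_normality` with `statistic` (K-squared),
#'   `p_value`, `z_skewness`, `z_kurtosis`, `skewness` (sqrt(b1)),
#'   `kurtosis` (b2) and `n`.
#' @export
test_normality <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson test requires n >= 8 (got ", n, ")",
         call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5            # sqrt(b1), the sample skewness
  b2 <- m4 / m2^2              # sample kurtosis

  # D'Agostino (1970) transform of skewness
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # Anscombe & Glynn (1983) transform of kurtosis
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1b2 * (2 / sqb1b2 + sqrt(1 + 4 / sqb1b2^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  structure(list(statistic = K2,
                 p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
                 z_skewness = z1, z_kurtosis = z2,
                 skewness = b1, kurtosis = b2, n = n),
            class = "ns_normality")
}

#' @export
print.ns_normality <- function(x, ...) {
  cat(sprintf("D'Agostino-Pearson omnibus test: K2 = %.4g, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Exponential least-squares regression
#'
#' Fits `y = a * exp(b * x)` by nonlinear least squares in the original
#' y-space (initialised from the log-linear fit on positive y), as used
#' to relate wasted-effort counts to the decoupled NeuroSync index.
#' `method = "log-linear"` instead returns the ordinary linear regression
#' of log(y) on x; with noiseless exponential data the two coincide.
#'
#' @param x Predictor — typically the NeuroSync index recomputed without
#'   wasted efforts, in percent.
#' @param y Response — wasted efforts (count or per minute); must be
#'   non-negative.
#' @param method `"nls"` (default) or `"log-linear"`.
#' @return An object of class `ns_expfit` with parameters `a`, `b`, the
#'   coefficient of determination `r2` (against the mean-y baseline, in
#'   original space), `n`, `fitted`, `residuals` and `converged`.
#'   Methods: `coef`, `predict`, `residuals`, `print`.
#' @export
fit_exponential <- function(x, y, method = c("nls", "log-linear")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("at least 3 points are required for the exponential fit",
         call. = FALSE)
  if (all(y == 0)) {
    warning("all responses are zero: degenerate fit (a = 0), ",
            "r2 undefined")
    return(structure(list(a = 0, b = 0, r2 = NA_real_, n = n,
                          fitted = rep(0, n), residuals = y - 0,
                          converged = TRUE, degenerate = TRUE,
                          method = method, data = list(x = x, y = y)),
                     class = "ns_expfit"))
  }
  pos <- y > 0
  if (sum(pos) < 2L)
    stop("need at least 2 positive responses to initialise the fit",
         call. = FALSE)
  ll <- stats::lm(log(y[pos]) ~ x[pos])
  a0 <- exp(stats::coef(ll)[[1]]); b0 <- stats::coef(ll)[[2]]
  if (method == "log-linear") {
    a <- a0; b <- b0; converged <- TRUE
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x),
                        start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("exponential fit did not converge: ", conditionMessage(e),
             " (start a=", signif(a0, 4), ", b=", signif(b0, 4), ")",
             call. = FALSE))
    cf <- stats::coef(fit)
    a <- cf[["a"]]; b <- cf[["b"]]
    converged <- fit$convInfo$isConv %||% TRUE
  }
  fitted <- a * exp(b * x)
  res <- y - fitted
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(a = a, b = b, r2 = r2, n = n, fitted = fitted,
                 residuals = res, converged = converged,
                 degenerate = FALSE, method = method,
                 data = list(x = x, y = y)),
            class = "ns_expfit")
}

#' @export
coef.ns_expfit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.ns_expfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$x else newdata
  object$a * exp(object$b * x)
}

#' @export
residuals.ns_expfit <- function(object, ...) object$residuals

#' @export
print.ns_expfit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential least-squares fit: y = %.*g * exp(%.*g * x)\n",
              digits, x$a, digits, x$b))
  cat(sprintf("  r2 = %s, n = %d (%s)\n",
              if (is.na(x$r2)) "NA" else sprintf("%.*g", digits, x$r2),
              x$n, x$method))
  invisible(x)
}

#' Write a multi-mode analysis report
#'
#' Serialises one or more mode results into `summary.json` (machine
#' readable, including full detector-parameter provenance) and
#' `summary.txt` (a human-readable pattern/timing/proportion report),
#' plus one per-breath CSV per mode.
#'
#' @param results A list of `ns_mode_result` (or `neurosync`) objects.
#' @param stats Optional named list of additional statistics results
#'   (e.g. from [compare_modes()] or [fit_exponential()]) to embed.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
render_report <- function(results, stats = NULL, dir) {
  if (inherits(results, c("ns_mode_result", "neurosync")))
    results <- list(results)
  if (!length(results)) stop("at least one mode result is required",
                             call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create '", dir, "'", call. = FALSE)
  as_mode <- function(r) {
    if (inherits(r, "neurosync"))
      structure(list(mode_label = r$meta$mode %||% "unlabelled",
                     report = r, pattern = r$pattern),
                class = "ns_mode_result")
    else r
  }
  results <- lapply(results, as_mode)
  labels <- vapply(results, `[[`, character(1), "mode_label")

  mode_json <- lapply(results, function(mr) {
    rp <- mr$report
    list(mode = mr$mode_label,
         n_breaths = rp$n_breaths,
         neurosync_pct = rp$neurosync_pct,
         neurosync_no_wasted_pct = rp$neurosync_no_wasted_pct,
         counts = as.list(rp$counts),
         wasted_per_min = rp$wasted_per_min,
         proportions = list(synchronous = rp$pct_synchronous,
                            dyssynchronous = rp$pct_dyssynchronous,
                            asynchronous = rp$pct_asynchronous),
         pattern = rp$pattern,
         density_grid = list(breaks = rp$density_grid$breaks,
                             counts = rp$density_grid$counts),
         provenance = list(detector = unclass(rp$params),
                           peep = rp$peep, combine = rp$combine,
                           window_s = rp$window_s,
                           box_threshold_pct = rp$box_threshold_pct))
  })
  stats_json <- if (!is.null(stats))
    lapply(stats, function(s) {
      if (inherits(s, "ns_friedman"))
        list(type = "friedman_dunn", statistic = s$statistic, df = s$df,
             p_value = s$p_value, dunn = s$dunn)
      else if (inherits(s, "ns_expfit"))
        list(type = "exponential_fit", a = s$a, b = s$b, r2 = s$r2,
             n = s$n)
      else s
    })
  jsonlite::write_json(list(modes = mode_json, stats = stats_json),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")

  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines("Patient-ventilator interaction report", con)
  writeLines(strrep("=", 60), con)
  for (mr in results) {
    writeLines("", con)
    s <- summary.neurosync(mr$report)
    writeLines(utils::capture.output(print(s)), con)
  }
  if (!is.null(stats)) {
    writeLines("", con); writeLines("Statistics", con)
    writeLines(strrep("-", 60), con)
    for (nm in names(stats))
      writeLines(c(nm, utils::capture.output(print(stats[[nm]]))), con)
  }
  for (i in seq_along(results)) {
    pb <- results[[i]]$report$per_breath
    safe <- gsub("[^A-Za-z0-9_-]+", "_", labels[i])
    utils::write.csv(
      pb[, c("breath_id", "klass", "trigger_error_pct",
             "cycleoff_error_pct", "breath_error_pct")],
      file.path(dir, paste0("breaths_", safe, ".csv")),
      row.names = FALSE, na = "")
  }
  invisible(dir)
}
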
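#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two paired measurement series as the Pearson
#' correlation penalized by location and scale shifts:
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. The 95% confidence interval uses the Fisher
#' z-transform with Lin's large-sample variance.
#'
#' Edge cases: if both series are constant and equal the coefficient is 1;
#' if both are constant but unequal it is 0, with a warning; fewer than 3
#' pairs is an error.
#'
#' @param x,y paired numeric vectors of equal length (>= 3), finite.
#' @param conf confidence level for the interval. Default 0.95.
#' @return List with `ccc`, `ci_low`, `ci_high`, `pearson_r`, `c_b` (the
#'   bias-correction factor, `ccc = r * c_b`), and `n`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # shifted: r = 1 but ccc < 1
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must be the same length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")

  mx <- mean(x); my <- mean(y)
  # population (1/n) moments, the standard definition
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2

  if (denom == 0) {  # both constant and equal
    return(list(ccc = 1, ci_low = 1, ci_high = 1, pearson_r = NA_real_,
                c_b = NA_real_, n = n))
  }
  if (sx2 == 0 && sy2 == 0) {  # both constant, unequal
    warning("both series constant but unequal; concordance is 0")
    return(list(ccc = 0, ci_low = NA_real_, ci_high = NA_real_,
                pearson_r = NA_real_, c_b = NA_real_, n = n))
  }

  ccc <- 2 * sxy / denom
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  c_b <- if (is.finite(r) && r != 0) ccc / r else NA_real_

  # Fisher-z CI with Lin's large-sample variance of z(ccc)
  ci <- c(NA_real_, NA_real_)
  if (is.finite(r) && abs(ccc) < 1 && r != 0) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    var_z <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(var_z) && var_z >= 0) {
      z <- atanh(ccc)
      half <- qnorm(1 - (1 - conf) / 2) * sqrt(var_z)
      ci <- tanh(c(z - half, z + half))
    }
  } else if (abs(ccc) == 1) {
    ci <- c(ccc, ccc)
  }
  list(ccc = ccc, ci_low = ci[1], ci_high = ci[2], pearson_r = r,
       c_b = c_b, n = n)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among `m` raters each ranking `n` cases, with the standard
#' mid-rank tie correction: ratings are converted to ranks within each
#' rater, and `W = 12 S / (m^2 (n^3 - n) - m T)` where `S` is the sum of
#' squared deviations of case rank sums from their mean and
#' `T = sum over raters of sum(t^3 - t)` over tie groups of size `t`.
#' Significance uses the chi-squared approximation
#' `chi2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' @param ratings numeric matrix, cases in rows, raters in columns
#'   (`n >= 2` rows, `m >= 2` columns).
#' @return List with `w`, `chi2`, `df`, `p`, `n`, `m`.
#' @examples
#' kendall_w(cbind(1:5, 1:5, 1:5))$w   # identical rankings: W = 1
#' @export
kendall_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); m <- ncol(ratings)
  if (n < 2L || m < 2L) stop("need at least 2 cases and 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be finite")

  ranks <- apply(ratings, 2, rank)  # mid-ranks within each rater
  rs <- rowSums(ranks)
  s <- sum((rs - mean(rs))^2)
  tie_term <- sum(apply(ranks, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_term
  if (denom <= 0) {
    # every rater gave all-equal ratings: no information to disagree
    warning("degenerate ratings (all raters constant); W defined as 1")
    w <- 1
  } else {
    w <- 12 * s / denom
  }
  chi2 <- m * (n - 1) * w
  df <- n - 1
  list(w = w, chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       n = n, m = m)
}

#' Coefficient of variation of repeated measurements
#'
#' Per-(case, observer) CV = sample SD of the replicates / mean x 100%.
#' The observer-level summary is the arithmetic mean of that observer's
#' per-case CVs (the median is also reported); subgroup summaries elsewhere
#' use medians of the per-case-per-observer CVs.
#'
#' @param table a measurement table: data.frame with columns `case_id`,
#'   `observer_id`, `replicate`, `volume_mm3` (see [read_measurement_table()]).
#' @return List with `per_case` (data.frame: case_id, observer_id,
#'   n_replicates, mean_volume, sd_volume, cv_percent) and `per_observer`
#'   (data.frame: observer_id, mean_cv_percent, median_cv_percent, n_cases).
#'   Cases with zero mean volume get `NA` CV.
#' @export
coefficient_of_variation <- function(table) {
  check_measurement_table(table, need_replicates = TRUE)
  key <- interaction(table$case_id, table$observer_id, drop = TRUE)
  per <- do.call(rbind, lapply(split(table, key), function(d) {
    mu <- mean(d$volume_mm3)
    s <- if (nrow(d) >= 2) sd(d$volume_mm3) else NA_real_
    data.frame(case_id = d$case_id[1], observer_id = d$observer_id[1],
               n_replicates = nrow(d), mean_volume = mu, sd_volume = s,
               cv_percent = if (!is.na(s) && mu > 0) s / mu * 100 else NA_real_)
  }))
  rownames(per) <- NULL
  obs <- do.call(rbind, lapply(split(per, per$observer_id), function(d) {
    data.frame(observer_id = d$observer_id[1],
               mean_cv_percent = mean(d$cv_percent, na.rm = TRUE),
               median_cv_percent = median(d$cv_percent, na.rm = TRUE),
               n_cases = nrow(d))
  }))
  rownames(obs) <- NULL
  list(per_case = per, per_observer = obs)
}

#' Bland-Altman agreement analysis
#'
#' For paired series the differences `d = x - y` give the bias (mean
#' difference), the sample SD of differences, the 95% limits of agreement
#' `bias +/- 1.96 SD`, and the repeatability coefficient `RC = 1.96 SD`
#' (so `rc / sd_diff` is 1.96 by construction).
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`, `rc`, `n`,
#'   plus `means` and `diffs` for plotting.
#' @examples
#' bland_altman(c(10, 12, 9), c(11, 11, 10))
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must be the same length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       rc = 1.96 * s, n = length(x),
       means = (x + y) / 2, diffs = d)
}

#' Paired Student's t-test on two measurement series
#'
#' Thin wrapper around [stats::t.test()] (paired, two-sided), returning just
#' the statistic and p-value. Zero variance of the differences is an error.
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must be the same length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (sd(x - y) == 0) stop("differences have zero variance; t is undefined")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# Mid-rank U statistic for group a vs b (U counts, for each (a_i, b_j) pair,
# a_i > b_j as 1 and ties as 1/2).
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For groups of at most 8 without ties the p-value
#' is exact, by full enumeration of all assignments of the pooled values to
#' the two groups; otherwise the normal approximation with tie correction is
#' used (via [stats::wilcox.test()] without continuity correction).
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max largest per-group size for the enumeration path.
#'   Default 8.
#' @return List with `u` (mid-rank U for group `a`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  u <- .u_stat(a, b)
  pooled <- c(a, b)
  no_ties <- !anyDuplicated(pooled)

  if (na <= exact_max && nb <= exact_max && no_ties) {
    # exact null distribution of U by enumerating all group-a index sets
    sets <- combn(na + nb, na)
    r <- rank(pooled)
    us <- apply(sets, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
    u_lo <- min(u, na * nb - u)
    u_hi <- na * nb - u_lo
    p <- sum(us <= u_lo | us >= u_hi) / ncol(sets)
    return(list(u = u, p = min(1, p), method = "exact"))
  }
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(u = u, p = wt$p.value, method = "normal")
}

# ---- measurement tables ------------------------------------------------

check_measurement_table <- function(table, need_replicates = FALSE) {
  needed <- c("case_id", "observer_id", "replicate", "volume_mm3")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("measurement table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(table$volume_mm3)) || any(table$volume_mm3 < 0))
    stop("`volume_mm3` must be finite and non-negative")
  key <- paste(table$case_id, table$observer_id, table$replicate)
  if (anyDuplicated(key))
    stop("(case_id, observer_id, replicate) must be unique")
  invisible(table)
}

#' Read / write a long-format measurement table (CSV)
#'
#' Columns: `case_id`, `observer_id`, `replicate`, `volume_mm3` (mm^3),
#' plus optional per-case metadata `is_complex`, `is_homogeneous`,
#' `is_multiple` (logical) and `location` (`pelvis`/`calyx`/`other`).
#' Comma separator, dot decimal, UTF-8. Volumes survive a write/read
#' round-trip exactly (written at full precision).
#'
#' @param path CSV file path.
#' @param table the data.frame to write.
#' @return `read_measurement_table`: the validated data.frame.
#' @export
read_measurement_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("is_complex", "is_homogeneous", "is_multiple"))
    if (cn %in% names(tab)) tab[[cn]] <- as.logical(tab[[cn]])
  check_measurement_table(tab)
  tab
}

#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(table, path) {
  check_measurement_table(table)
  tab <- table
  # full-precision decimal strings so the round-trip is exact
  tab$volume_mm3 <- vapply(tab$volume_mm3, format, character(1), digits = 17)
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# cases x observers matrix of aggregated volumes
.case_observer_matrix <- function(table, aggregation) {
  cases <- sort(unique(table$case_id))
  obs <- sort(unique(table$observer_id))
  m <- matrix(NA_real_, length(cases), length(obs),
              dimnames = list(as.character(cases), as.character(obs)))
  agg_fun <- if (aggregation == "median") median else mean
  for (i in seq_along(cases)) for (j in seq_along(obs)) {
    v <- table$volume_mm3[table$case_id == cases[i] &
                            table$observer_id == obs[j]]
    if (length(v)) m[i, j] <- agg_fun(v)
  }
  m
}

#' Inter-/intra-observer agreement study
#'
#' Runs the full agreement analysis of a repeated-measurement study on one
#' measurement table: pairwise Lin concordance (with CI) and paired t-tests
#' between observers, overall Kendall W across observers, per-observer
#' coefficients of variation and intra-observer Kendall W (concordance of
#' the replicate-wise rankings of the cases within one observer), pairwise
#' Bland-Altman panels, and Mann-Whitney comparisons of per-case CV between
#' metadata subgroups (complexity, homogeneity, multiplicity).
#'
#' `aggregation = "median"` collapses replicates to per-case medians before
#' the between-observer analyses (the only mode available when just one
#' summary value per case and observer is known); `"raw"` pairs the raw
#' values by (case, replicate). Replicate-dependent analyses (CV,
#' intra-observer W) run only when replicates are present; subgroup analyses
#' run only when metadata columns are present, otherwise they are skipped
#' with a warning.
#'
#' @param table measurement table (see [read_measurement_table()]).
#' @param aggregation `"median"` (default) or `"raw"`.
#' @return An object of class `stone_agreement`: list with `pairwise`
#'   (data.frame: pair, lin_ccc, ci_low, ci_high, t, t_p, bias, sd_diff,
#'   loa_low, loa_high, rc), `overall` (Kendall W list), `per_observer`
#'   (CV and intra-observer W per observer), `subgroups` (per-factor median
#'   CVs and Mann-Whitney p), `bland_altman` (full per-pair lists for
#'   plotting), `case_matrix`, `aggregation`, `n_cases`, `n_observers`.
#' @examples
#' tab <- expand.grid(case_id = 1:6, observer_id = c("A", "B"), replicate = 1:2)
#' tab$volume_mm3 <- 100 * tab$case_id + rnorm(nrow(tab), sd = 2)
#' agreement_study(tab)
#' @export
agreement_study <- function(table, aggregation = c("median", "raw")) {
  aggregation <- match.arg(aggregation)
  check_measurement_table(table)
  obs <- sort(unique(table$observer_id))
  if (length(obs) < 2L) stop("need at least 2 observers")

  cm <- .case_observer_matrix(table, if (aggregation == "median") "median" else "mean")
  if (any(is.na(cm))) stop("every case must be measured by every observer")

  # pairwise analyses on the aggregated (or raw, paired) values
  pairs <- combn(length(obs), 2)
  pair_rows <- list(); ba_full <- list()
  for (k in seq_len(ncol(pairs))) {
    o1 <- obs[pairs[1, k]]; o2 <- obs[pairs[2, k]]
    if (aggregation == "median") {
      x <- cm[, as.character(o1)]; y <- cm[, as.character(o2)]
    } else {
      t1 <- table[table$observer_id == o1, ]
      t2 <- table[table$observer_id == o2, ]
      key1 <- paste(t1$case_id, t1$replicate)
      key2 <- paste(t2$case_id, t2$replicate)
      common <- intersect(key1, key2)
      x <- t1$volume_mm3[match(common, key1)]
      y <- t2$volume_mm3[match(common, key2)]
    }
    cc <- lin_ccc(x, y)
    tt <- tryCatch(paired_t_test(x, y),
                   error = function(e) list(t = NA_real_, df = NA_real_, p = NA_real_))
    ba <- bland_altman(x, y)
    pair_name <- paste(o1, "vs", o2)
    pair_rows[[k]] <- data.frame(
      pair = pair_name, observer_1 = as.character(o1),
      observer_2 = as.character(o2),
      lin_ccc = cc$ccc, ci_low = cc$ci_low, ci_high = cc$ci_high,
      t = tt$t, t_p = tt$p,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high, rc = ba$rc,
      stringsAsFactors = FALSE)
    ba_full[[pair_name]] <- ba
  }
  pairwise <- do.call(rbind, pair_rows)

  overall <- kendall_w(cm)

  # replicate-dependent: CV and intra-observer W
  reps_per <- table(paste(table$case_id, table$observer_id))
  has_reps <- all(reps_per >= 2)
  cv <- NULL; per_observer <- NULL
  if (has_reps) {
    cv <- coefficient_of_variation(table)
    per_observer <- cv$per_observer
    per_observer$intra_w <- NA_real_
    per_observer$intra_p <- NA_real_
    for (i in seq_len(nrow(per_observer))) {
      o <- per_observer$observer_id[i]
      t_o <- table[table$observer_id == o, ]
      # cases x replicates matrix: each replicate sweep is one "rater"
      rm_ <- .replicate_matrix(t_o)
      if (!is.null(rm_)) {
        kw <- kendall_w(rm_)
        per_observer$intra_w[i] <- kw$w
        per_observer$intra_p[i] <- kw$p
      }
    }
  }

  subgroups <- .subgroup_analyses(table, cv)

  structure(list(
    pairwise = pairwise, overall = overall, per_observer = per_observer,
    per_case_cv = if (!is.null(cv)) cv$per_case else NULL,
    subgroups = subgroups, bland_altman = ba_full,
    case_matrix = cm, aggregation = aggregation,
    n_cases = nrow(cm), n_observers = length(obs)
  ), class = "stone_agreement")
}

# cases x replicates volume matrix for one observer (NULL if ragged)
.replicate_matrix <- function(t_o) {
  cases <- sort(unique(t_o$case_id))
  reps <- sort(unique(t_o$replicate))
  if (length(reps) < 2L || length(cases) < 2L) return(NULL)
  m <- matrix(NA_real_, length(cases), length(reps))
  for (i in seq_along(cases)) for (j in seq_along(reps)) {
    v <- t_o$volume_mm3[t_o$case_id == cases[i] & t_o$replicate == reps[j]]
    if (length(v) == 1L) m[i, j] <- v
  }
  if (any(is.na(m))) return(NULL)
  m
}

# median CV per level + Mann-Whitney, for each available metadata factor
.subgroup_analyses <- function(table, cv) {
  factors <- list(
    complexity = c("is_complex", "complex", "plain"),
    homogeneity = c("is_homogeneous", "homogeneous", "heterogeneous"),
    multiplicity = c("is_multiple", "multiple", "unique")
  )
  if (is.null(cv)) return(NULL)
  per <- cv$per_case
  meta_cols <- intersect(c("is_complex", "is_homogeneous", "is_multiple"),
                         names(table))
  if (length(meta_cols) == 0L) {
    warning("no metadata columns; subgroup analyses skipped")
    return(NULL)
  }
  meta <- unique(table[c("case_id", meta_cols)])
  per <- merge(per, meta, by = "case_id", all.x = TRUE)
  out <- list()
  for (nm in names(factors)) {
    col <- factors[[nm]][1]
    if (!col %in% names(per)) next
    flag <- per[[col]]
    if (all(is.na(flag))) next
    cv_true <- per$cv_percent[flag %in% TRUE]
    cv_false <- per$cv_percent[flag %in% FALSE]
    cv_true <- cv_true[is.finite(cv_true)]
    cv_false <- cv_false[is.finite(cv_false)]
    if (length(cv_true) == 0L || length(cv_false) == 0L) next
    mw <- mann_whitney_u(cv_true, cv_false)
    out[[nm]] <- list(
      level_true = factors[[nm]][2], level_false = factors[[nm]][3],
      median_cv_true = median(cv_true), median_cv_false = median(cv_false),
      n_true = length(cv_true), n_false = length(cv_false),
      u = mw$u, p = mw$p, method = mw$method)
  }
  if (length(out) == 0L) {
    warning("metadata present but unusable; subgroup analyses skipped")
    return(NULL)
  }
  out
}

#' @export
print.stone_agreement <- function(x, ...) {
  cat(sprintf("<stone_agreement> %d cases x %d observers (aggregation: %s)\n",
              x$n_cases, x$n_observers, x$aggregation))
  cat(sprintf("  Overall Kendall W = %.4f (chi2 = %.1f, df = %d, p = %.3g)\n",
              x$overall$w, x$overall$chi2, x$overall$df, x$overall$p))
  for (i in seq_len(nrow(x$pairwise))) {
    p <- x$pairwise[i, ]
    cat(sprintf("  %s: Lin CCC %.4f (%.4f-%.4f), bias %.1f mm^3, RC %.1f, t p = %.2f\n",
                p$pair, p$lin_ccc, p$ci_low, p$ci_high, p$bias, p$rc, p$t_p))
  }
  if (!is.null(x$per_observer)) {
    for (i in seq_len(nrow(x$per_observer))) {
      o <- x$per_observer[i, ]
      cat(sprintf("  observer %s: mean CV %.1f%%, intra-observer W %s\n",
                  o$observer_id, o$mean_cv_percent,
                  ifelse(is.na(o$intra_w), "n/a", sprintf("%.3f", o$intra_w))))
    }
  }
  if (!is.null(x$subgroups)) {
    for (nm in names(x$subgroups)) {
      s <- x$subgroups[[nm]]
      cat(sprintf("  %s: median CV %s %.1f%% vs %s %.1f%% (Mann-Whitney p = %.3g)\n",
                  nm, s$level_true, s$median_cv_true,
                  s$level_false, s$median_cv_false, s$p))
    }
  }
  invisible(x)
}

#' @export
summary.stone_agreement <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Bland-Altman plot of an agreement study
#'
#' One mean-vs-difference panel per observer pair, with the bias and 95%
#' limits-of-agreement lines.
#'
#' @param x a `stone_agreement`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stone_agreement <- function(x, ...) {
  nb <- length(x$bland_altman)
  old <- par(mfrow = c(1, nb), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (nm in names(x$bland_altman)) {
    ba <- x$bland_altman[[nm]]
    plot(ba$means, ba$diffs, xlab = "Mean volume (mm^3)",
         ylab = "Difference (mm^3)", main = nm, pch = 19, ...)
    abline(h = ba$bias, lty = 1)
    abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  }
  invisible(x)
}

#' Write an agreement report to JSON or Markdown
#'
#' @param x a `stone_agreement`.
#' @param json,markdown output paths (either may be `NULL`).
#' @return Invisibly, the list of paths written.
#' @export
write_agreement_report <- function(x, json = NULL, markdown = NULL) {
  stopifnot(inherits(x, "stone_agreement"))
  if (!is.null(json)) {
    payload <- list(
      n_cases = x$n_cases, n_observers = x$n_observers,
      aggregation = x$aggregation,
      overall_kendall_w = x$overall[c("w", "chi2", "df", "p")],
      pairwise = x$pairwise,
      per_observer = x$per_observer,
      subgroups = x$subgroups
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(markdown)) {
    lines <- c(
      "# Observer agreement report", "",
      sprintf("%d cases x %d observers (aggregation: %s)",
              x$n_cases, x$n_observers, x$aggregation), "",
      sprintf("Overall Kendall W: %.4f (p = %.3g)", x$overall$w, x$overall$p),
      "", "| Pair | Lin CCC | 95% CI | Bias (mm^3) | RC (mm^3) | t-test p |",
      "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(x$pairwise))) {
      p <- x$pairwise[i, ]
      lines <- c(lines, sprintf("| %s | %.4f | %.4f-%.4f | %.1f | %.1f | %.2f |",
                                p$pair, p$lin_ccc, p$ci_low, p$ci_high,
                                p$bias, p$rc, p$t_p))
    }
    if (!is.null(x$per_observer)) {
      lines <- c(lines, "", "| Observer | Mean CV (%) | Intra-observer W |",
                 "|---|---|---|")
      for (i in seq_len(nrow(x$per_observer))) {
        o <- x$per_observer[i, ]
        lines <- c(lines, sprintf("| %s | %.1f | %s |", o$observer_id,
                                  o$mean_cv_percent,
                                  ifelse(is.na(o$intra_w), "n/a",
                                         sprintf("%.3f", o$intra_w))))
      }
    }
    writeLines(lines, markdown)
  }
  invisible(list(json = json, markdown = markdown))
}
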
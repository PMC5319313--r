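# Batch pipeline: read study records, run per-study Bayesian reanalysis,
# classify evidence, optionally add the hierarchical fit, and tally flags.

.test_types <- c("one_sample_t", "two_sample_t", "correlation", "contingency")

#' Read study records from CSV
#'
#' Reads and validates a study CSV with columns `study_id`, `test_type`
#' (one of `one_sample_t`, `two_sample_t`, `correlation`, `contingency`),
#' `t`, `n1`, `n2`, `r_obs`, `table`, `direction`. Only the fields a row's
#' `test_type` requires must be present in that row; validation errors name
#' the row and the missing/invalid column. The `table` cell holds
#' semicolon-delimited row-major counts of a square contingency table
#' (e.g. `"30;10;8;32"` for 2 x 2).
#'
#' @param path path to the CSV file.
#' @return a data frame of validated records with a parsed `table_counts`
#'   list-column for contingency rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_studies_csv(fixture_special_issue_like(), f)
#' head(read_studies_csv(f))
#' @export
read_studies_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("cannot read study file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("study_id", "test_type") %in% names(df)))
    stop_invalid("study CSV needs at least columns study_id and test_type")
  for (col in c("t", "n1", "n2", "r_obs", "table", "direction"))
    if (!col %in% names(df)) df[[col]] <- NA
  if (nrow(df) == 0L) { df$table_counts <- list(); return(df) }
  df$direction <- ifelse(is.na(df$direction), 1, df$direction)
  errs <- character(0)
  tabs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    tt <- df$test_type[i]
    id <- df$study_id[i]
    bad <- function(col) errs <<- c(errs, sprintf(
      "row %d (id '%s', %s): missing or invalid '%s'", i, id, tt, col))
    if (!tt %in% .test_types) {
      errs <- c(errs, sprintf("row %d (id '%s'): unknown test_type '%s'", i, id, tt))
      next
    }
    if (!df$direction[i] %in% c(-1, 1)) bad("direction")
    if (tt %in% c("one_sample_t", "two_sample_t")) {
      if (is.na(df$t[i])) bad("t")
      if (is.na(df$n1[i]) || df$n1[i] < 2) bad("n1")
      if (tt == "two_sample_t" && (is.na(df$n2[i]) || df$n2[i] < 2)) bad("n2")
      if (tt == "one_sample_t" && !is.na(df$n2[i]) && df$n2[i] != 0) bad("n2")
    } else if (tt == "correlation") {
      if (is.na(df$r_obs[i]) || abs(df$r_obs[i]) >= 1) bad("r_obs")
      if (is.na(df$n1[i]) || df$n1[i] < 3) bad("n1")
    } else if (tt == "contingency") {
      cell <- df$table[i]
      counts <- suppressWarnings(as.numeric(strsplit(
        as.character(cell), ";", fixed = TRUE)[[1]]))
      k <- sqrt(length(counts))
      if (is.na(cell) || length(counts) < 4L || any(is.na(counts)) ||
          k != round(k)) bad("table")
      else tabs[[i]] <- matrix(counts, nrow = k, byrow = TRUE)
    }
  }
  if (length(errs)) stop_invalid("invalid study records:\n  ",
                                 paste(errs, collapse = "\n  "))
  df$table_counts <- tabs
  df
}

#' Write study records to CSV
#'
#' Inverse of [read_studies_csv()]; contingency tables are serialized as
#' semicolon-delimited row-major counts.
#'
#' @param studies a study data frame (as produced by
#'   [fixture_special_issue_like()], [simulate_studies()]`$studies`, or
#'   [read_studies_csv()]).
#' @param path output path.
#' @export
write_studies_csv <- function(studies, path) {
  df <- as.data.frame(studies)
  if (!is.null(df$table_counts)) {
    df$table <- vapply(df$table_counts, function(m)
      if (is.null(m)) NA_character_ else paste(t(m), collapse = ";"),
      character(1))
    df$table_counts <- NULL
  }
  for (col in c("t", "n1", "n2", "r_obs", "table", "direction"))
    if (!col %in% names(df)) df[[col]] <- NA
  utils::write.csv(
    df[, c("study_id", "test_type", "t", "n1", "n2", "r_obs", "table",
           "direction")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Jeffreys evidence category of a Bayes factor
#'
#' Maps a Bayes factor onto Jeffreys's descriptive evidence categories with
#' the symmetric boundaries 1, 3, 10, 30, 100 (and their reciprocals for
#' support of H0): anecdotal (1-3), moderate (3-10), strong (10-30), very
#' strong (30-100), extreme (>100). A Bayes factor sitting exactly on a
#' boundary is assigned to the weaker category (BF = 3 is still
#' `anecdotal_H1`); BF = 1 is `none`.
#'
#' @param bf a positive number or a `bf_result`.
#' @return a length-1 character label, one of `extreme_H1`,
#'   `very_strong_H1`, `strong_H1`, `moderate_H1`, `anecdotal_H1`, `none`,
#'   `anecdotal_H0`, `moderate_H0`, `strong_H0`, `very_strong_H0`,
#'   `extreme_H0`.
#' @examples
#' classify_evidence(576)   # extreme_H1
#' classify_evidence(0.2)   # moderate_H0
#' @export
classify_evidence <- function(bf) {
  if (inherits(bf, "bf_result")) bf <- bf$value
  if (!is.numeric(bf) || length(bf) != 1L || is.na(bf) || bf <= 0)
    stop_invalid("'bf' must be a single positive number")
  if (bf == 1) return("none")
  h1 <- bf > 1
  b <- if (h1) bf else 1 / bf
  lab <- c("anecdotal", "moderate", "strong", "very_strong", "extreme")[
    findInterval(b, c(1, 3, 10, 30, 100), left.open = TRUE)]
  paste0(lab, if (h1) "_H1" else "_H0")
}

pipeline_row <- function(rec, prior_width, kappa, alpha, level, seed) {
  tt <- rec$test_type
  dir <- rec$direction
  side <- if (dir > 0) "positive" else "negative"
  out <- list(bf = NA_real_, bf_pair = NA_character_,
              es_median = NA_real_, es_lo = NA_real_, es_hi = NA_real_,
              r2_median = NA_real_, r2_lo = NA_real_, r2_hi = NA_real_)
  if (tt %in% c("one_sample_t", "two_sample_t")) {
    ts <- ttest_summary(rec$t, rec$n1, if (tt == "one_sample_t") 0 else rec$n2,
                        direction = dir, id = rec$study_id)
    bf <- bf_onesided_ttest(ts, jzs_prior(prior_width), side = side)
    dp <- delta_posterior(ts, jzs_prior(prior_width), level = level)
    r2 <- rho2_from_delta(dp, ts$n1, ts$n2, level = level)
    # recode so the predicted direction is positive
    es <- c(dp$median, dp$ci_low, dp$ci_high) * dir
    if (dir < 0) es <- es[c(1, 3, 2)]
    out[c("bf", "bf_pair")] <- list(bf$value, bf$pair)
    out[c("es_median", "es_lo", "es_hi")] <- as.list(es)
    out[c("r2_median", "r2_lo", "r2_hi")] <-
      list(r2$median, r2$ci_low, r2$ci_high)
  } else if (tt == "correlation") {
    bf <- bf_correlation(rec$r_obs, rec$n1, kappa = kappa, side = side)
    rp <- rho_posterior(rec$r_obs, rec$n1, kappa = kappa, level = level)
    r2 <- {
      wt <- local({
        dx <- diff(rp$values); w <- rp$weights; n <- length(w)
        ww <- numeric(n)
        ww[1] <- w[1] * dx[1] / 2; ww[n] <- w[n] * dx[n - 1] / 2
        ww[2:(n - 1)] <- w[2:(n - 1)] * (dx[-1] + dx[-(n - 1)]) / 2
        ww
      })
      v <- rp$values^2
      qs <- weighted_quantile(v, wt, c((1 - level) / 2, 0.5, (1 + level) / 2))
      list(median = qs[2], lo = qs[1], hi = qs[3])
    }
    es <- c(rp$median, rp$ci_low, rp$ci_high) * dir
    if (dir < 0) es <- es[c(1, 3, 2)]
    out[c("bf", "bf_pair")] <- list(bf$value, bf$pair)
    out[c("es_median", "es_lo", "es_hi")] <- as.list(es)
    out[c("r2_median", "r2_lo", "r2_hi")] <- list(r2$median, r2$lo, r2$hi)
  } else if (tt == "contingency") {
    pp <- phi2_posterior(rec$table_counts[[1]], alpha = alpha, seed = seed,
                         level = level)
    out[c("r2_median", "r2_lo", "r2_hi")] <-
      list(pp$median, pp$ci_low, pp$ci_high)
  } else stop_invalid("unknown test_type: ", tt)
  out
}

#' Run the full Bayesian reassessment pipeline
#'
#' For every study record: the appropriate directional Bayes factor (JZS
#' for t-tests, stretched-beta for correlations; contingency rows get
#' effect-size estimation only), the directed effect-size posterior
#' (recoded so the predicted direction is positive), the undirected
#' variance-explained posterior (rho-squared / phi-squared), the Jeffreys
#' evidence category, and the interval flags the replication literature
#' tallies: does the central CI exclude zero in the predicted direction,
#' and does the variance-explained CI contain values above 0.05 / 0.10?
#' Per-study failures are caught, recorded in the `error` column, and do
#' not abort the batch; tallies count successful rows only.
#'
#' @param records study records from [read_studies_csv()],
#'   [simulate_studies()] or [fixture_special_issue_like()].
#' @param prior_width Cauchy prior width for t-test effect sizes.
#' @param kappa stretched-beta prior width for correlations.
#' @param alpha Dirichlet concentration for contingency tables.
#' @param with_meta also fit the hierarchical meta-analysis on the t-test
#'   subset (needs >= 2 t-tests) and append shrinkage columns.
#' @param level credible level.
#' @param seed integer seed for the Monte Carlo components.
#' @param meta_cfg a [meta_config()] for the optional hierarchical fit;
#'   its seed is overridden by `seed`.
#' @return an object of class `replication_report`: list with `rows` (per
#'   study results and flags), `tallies` (aggregate counts, each equal to
#'   the sum of its row flag), optional `meta` and `shrinkage`, and
#'   `metadata` (seeds, priors, versions).
#' @examples
#' \donttest{
#' rep <- run_pipeline(fixture_special_issue_like()[1:3, ], seed = 1)
#' rep$rows[, c("study_id", "bf", "category")]
#' }
#' @export
run_pipeline <- function(records, prior_width = 2^-0.5, kappa = 1, alpha = 1,
                         with_meta = FALSE, level = 0.95, seed = 1L,
                         meta_cfg = meta_config()) {
  if (inherits(records, "simulated_studies")) records <- records$studies
  records <- as.data.frame(records)
  if (nrow(records) < 1L) stop_invalid("need at least one study record")
  if (is.null(records$direction)) records$direction <- 1
  if (is.null(records$table_counts)) records$table_counts <-
    vector("list", nrow(records))
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    res <- tryCatch(pipeline_row(rec, prior_width, kappa, alpha, level,
                                 seed = seed + i),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows[[i]] <- data.frame(
        study_id = rec$study_id, test_type = rec$test_type, bf = NA_real_,
        bf_pair = NA_character_, category = NA_character_,
        es_median = NA_real_, es_lo = NA_real_, es_hi = NA_real_,
        r2_median = NA_real_, r2_lo = NA_real_, r2_hi = NA_real_,
        ci_excludes_zero = NA, r2_above_05 = NA, r2_above_10 = NA,
        error = res, stringsAsFactors = FALSE)
    } else {
      cat_lab <- if (is.na(res$bf)) NA_character_ else classify_evidence(res$bf)
      rows[[i]] <- data.frame(
        study_id = rec$study_id, test_type = rec$test_type, bf = res$bf,
        bf_pair = res$bf_pair, category = cat_lab,
        es_median = res$es_median, es_lo = res$es_lo, es_hi = res$es_hi,
        r2_median = res$r2_median, r2_lo = res$r2_lo, r2_hi = res$r2_hi,
        ci_excludes_zero = if (is.na(res$es_lo)) NA else res$es_lo > 0,
        r2_above_05 = res$r2_hi > 0.05, r2_above_10 = res$r2_hi > 0.10,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  ok <- is.na(rows$error)
  tallies <- list(
    n_studies = nrow(rows), n_failed = sum(!ok),
    ci_excludes_zero = sum(rows$ci_excludes_zero[ok], na.rm = TRUE),
    r2_above_05 = sum(rows$r2_above_05[ok], na.rm = TRUE),
    r2_above_10 = sum(rows$r2_above_10[ok], na.rm = TRUE),
    categories = table(factor(rows$category[ok], levels = c(
      "extreme_H1", "very_strong_H1", "strong_H1", "moderate_H1",
      "anecdotal_H1", "none", "anecdotal_H0", "moderate_H0", "strong_H0",
      "very_strong_H0", "extreme_H0"))))
  out <- list(rows = rows, tallies = tallies,
              metadata = list(prior_width = prior_width, kappa = kappa,
                              alpha = alpha, level = level, seed = seed,
                              package_version =
                                as.character(utils::packageVersion("bayesrep")),
                              r_version = R.version.string))
  tmask <- ok & rows$test_type %in% c("one_sample_t", "two_sample_t")
  if (with_meta && sum(tmask) >= 2L) {
    sub <- records[tmask, , drop = FALSE]
    # recode to predicted-positive before pooling
    sub$t <- sub$t * sub$direction
    sub$n2[sub$test_type == "one_sample_t"] <- 0L
    meta_cfg$seed <- as.integer(seed)
    fit <- fit_meta(sub, meta_cfg)
    indiv <- lapply(seq_len(nrow(sub)), function(j)
      delta_posterior(ttest_summary(sub$t[j], sub$n1[j], sub$n2[j]),
                      jzs_prior(prior_width), level = level))
    out$meta <- fit
    out$shrinkage <- shrinkage_table(fit, indiv, level = level)
  }
  class(out) <- "replication_report"
  out
}

#' @export
print.replication_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("Replication report: %d studies (%d failed)\n",
              t$n_studies, t$n_failed))
  cat(sprintf("  CI excludes zero in predicted direction: %d\n",
              t$ci_excludes_zero))
  cat(sprintf("  variance-explained CI contains > 0.05: %d; > 0.10: %d\n",
              t$r2_above_05, t$r2_above_10))
  bf_ok <- !is.na(x$rows$category)
  if (any(bf_ok)) {
    h1 <- sum(x$rows$bf[bf_ok] > 3)
    h0 <- sum(x$rows$bf[bf_ok] < 1)
    cat(sprintf("  Bayes factors: %d of %d with BF > 3 (non-anecdotal H1), %d with BF < 1\n",
                h1, sum(bf_ok), h0))
  }
  if (!is.null(x[["meta"]])) print(x[["meta"]])
  invisible(x)
}
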
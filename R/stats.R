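#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Observations are individual contractions. Fits a one-way fixed-effects
#' ANOVA of the requested feature on group; the full Tukey-Kramer pairwise
#' table (studentized-range distribution, valid for unequal group sizes) is
#' returned regardless of the omnibus outcome, together with a significance
#' gate flag (`gate_passed = p < alpha`). Groups with fewer than 2
#' observations are dropped with a warning.
#'
#' @param table phase-feature data.frame.
#' @param metric,source,phase row filters (e.g. `"f_median"`, `"stft80"`,
#'   `"derecruitment"`).
#' @param alpha omnibus significance level (default 0.05).
#' @return a `stat_result` with fields `test`, `statistic` (F), `df`,
#'   `p_value`, `gate_passed`, and `pairwise` (group1, group2, diff,
#'   p_value for every unordered pair).
#' @export
anova_tukey <- function(table, metric, source, phase, alpha = 0.05) {
  dat <- table[table$metric == metric & table$source == source &
                 table$phase == phase & !is.na(table$value), ]
  counts <- table(dat$group)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    dat <- dat[!dat$group %in% small, ]
  }
  if (length(unique(dat$group)) < 2)
    stop("need at least 2 groups with at least 2 observations each")
  dat$group <- factor(dat$group)
  fit <- stats::aov(value ~ group, data = dat)
  s <- summary(fit)[[1]]
  fstat <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                         diff = tk[, "diff"], p_value = tk[, "p adj"],
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  structure(
    list(test = "anova", statistic = fstat,
         df = c(s[["Df"]][1], s[["Df"]][2]), p_value = p,
         gate_passed = is.finite(p) && p < alpha,
         pairwise = pairwise,
         metric = metric, source = source, phase = phase),
    class = "stat_result"
  )
}

#' One-way MANOVA on the bivariate frequency-energy response
#'
#' Tests group differences jointly on mean instantaneous frequency and
#' mean instantaneous energy (Wilks' Lambda with its F approximation;
#' Pillai available as an option). Rows are matched per
#' (subject, burst) key.
#'
#' @param table phase-feature data.frame containing `inst_freq_mean` and
#'   `inst_energy_mean` rows for `source` and `phase`.
#' @param source,phase row filters.
#' @param statistic `"Wilks"` (default) or `"Pillai"`.
#' @return a `stat_result` with the multivariate statistic, approximate F,
#'   degrees of freedom and p-value.
#' @export
manova_pairs <- function(table, source, phase, statistic = c("Wilks", "Pillai")) {
  statistic <- match.arg(statistic)
  dat <- table[table$source == source & table$phase == phase, ]
  wf <- dat[dat$metric == "inst_freq_mean", c("subject", "group", "burst_id", "value")]
  we <- dat[dat$metric == "inst_energy_mean", c("subject", "burst_id", "value")]
  names(wf)[4] <- "freq"
  names(we)[3] <- "energy"
  wide <- merge(wf, we, by = c("subject", "burst_id"))
  wide <- wide[stats::complete.cases(wide), ]
  if (length(unique(wide$group)) < 2) stop("need at least 2 groups")
  for (v in c("freq", "energy"))
    if (all(tapply(wide[[v]], wide$group, stats::var) < .Machine$double.eps))
      stop("singular within-group covariance: metric ", v, " is degenerate")
  wide$group <- factor(wide$group)
  fit <- stats::manova(cbind(freq, energy) ~ group, data = wide)
  s <- summary(fit, test = statistic)$stats
  structure(
    list(test = "manova", statistic = s[1, statistic],
         approx_f = s[1, "approx F"],
         df = c(s[1, "num Df"], s[1, "den Df"]), p_value = s[1, "Pr(>F)"],
         source = source, phase = phase),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result:%s> statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Step-down Holm correction: p-values are sorted ascending, the i-th is
#' multiplied by `m - i + 1`, monotonicity is enforced by a running
#' maximum, values are capped at 1, and the original order is restored.
#' Delegates the arithmetic to [stats::p.adjust()] after validating the
#' input.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numbers in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' Run the full phase-resolved statistical battery
#'
#' For spectrogram/CWT sources (any source whose rows carry `f_mean` /
#' `f_median`): one ANOVA + Tukey per metric and phase. For IMF sources:
#' per mode and phase a MANOVA gate on the bivariate frequency-energy
#' response; the per-variable follow-up ANOVAs across all
#' (mode, phase, metric) cells form one family adjusted by the Holm
#' step-down correction (plain Bonferroni via `correction`), and post hoc
#' Tukey tables are emitted only where the MANOVA gate passed and the
#' adjusted ANOVA p-value stays below `alpha`.
#'
#' @param table phase-feature data.frame.
#' @param sources character vector of source tags to analyse (default: all
#'   present in the table).
#' @param alpha significance level (default 0.05).
#' @param correction `"holm"` (default) or `"bonferroni"` for the IMF ANOVA
#'   family.
#' @param unit `"burst"` (default; contractions are the observation unit)
#'   or `"subject"` (aggregate to per-subject means first).
#' @return list with `results` (named list of `stat_result`s), `anova_family`
#'   (data.frame of the IMF ANOVA family with raw and adjusted p),
#'   and `pairwise` (tidy data.frame: source, metric, phase, group1,
#'   group2, diff, p_value, significant).
#' @export
run_stat_battery <- function(table, sources = NULL, alpha = 0.05,
                             correction = c("holm", "bonferroni"),
                             unit = c("burst", "subject")) {
  correction <- match.arg(correction)
  unit <- match.arg(unit)
  if (unit == "subject") {
    agg <- stats::aggregate(value ~ subject + group + phase + source + metric,
                            data = table, FUN = mean, na.rm = TRUE)
    agg$burst_id <- 1L
    table <- agg
  }
  present <- unique(table$source)
  if (is.null(sources)) sources <- present
  missing_src <- setdiff(sources, present)
  if (length(missing_src) > 0) {
    message("skipping missing source(s): ", paste(missing_src, collapse = ", "))
    sources <- intersect(sources, present)
  }
  phases <- c("recruitment", "sustained", "derecruitment")
  results <- list()
  pairwise <- list()
  fam_rows <- list()
  for (src in sources) {
    sub <- table[table$source == src, ]
    metrics <- unique(sub$metric)
    if (any(c("f_mean", "f_median") %in% metrics)) {
      for (metric in intersect(c("f_mean", "f_median"), metrics)) {
        for (phase in phases) {
          res <- tryCatch(anova_tukey(table, metric, src, phase, alpha),
                          error = function(e) NULL)
          if (is.null(res)) {
            message("skipping ", src, "/", metric, "/", phase,
                    ": insufficient data")
            next
          }
          results[[paste(src, metric, phase, sep = ".")]] <- res
          pw <- res$pairwise
          pw$significant <- res$gate_passed & pw$p_value < alpha
          pairwise[[length(pairwise) + 1L]] <-
            cbind(source = src, metric = metric, phase = phase, pw)
        }
      }
    } else {
      for (phase in phases) {
        man <- tryCatch(manova_pairs(table, src, phase),
                        error = function(e) NULL)
        if (is.null(man)) next
        results[[paste(src, "manova", phase, sep = ".")]] <- man
        for (metric in intersect(c("inst_freq_mean", "inst_energy_mean"), metrics)) {
          res <- tryCatch(anova_tukey(table, metric, src, phase, alpha),
                          error = function(e) NULL)
          if (is.null(res)) next
          results[[paste(src, metric, phase, sep = ".")]] <- res
          fam_rows[[length(fam_rows) + 1L]] <- data.frame(
            source = src, metric = metric, phase = phase,
            p_raw = res$p_value, manova_p = man$p_value,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  anova_family <- if (length(fam_rows) > 0) do.call(rbind, fam_rows) else NULL
  if (!is.null(anova_family)) {
    anova_family$p_adj <- if (correction == "holm")
      holm_adjust(anova_family$p_raw)
    else pmin(anova_family$p_raw * nrow(anova_family), 1)
    for (r in seq_len(nrow(anova_family))) {
      key <- paste(anova_family$source[r], anova_family$metric[r],
                   anova_family$phase[r], sep = ".")
      res <- results[[key]]
      gate <- anova_family$manova_p[r] < alpha && anova_family$p_adj[r] < alpha
      if (gate) {
        pw <- res$pairwise
        pw$significant <- pw$p_value < alpha
        pairwise[[length(pairwise) + 1L]] <-
          cbind(source = anova_family$source[r], metric = anova_family$metric[r],
                phase = anova_family$phase[r], pw)
      }
    }
  }
  pairwise <- if (length(pairwise) > 0) do.call(rbind, pairwise) else
    data.frame(source = character(), metric = character(), phase = character(),
               group1 = character(), group2 = character(), diff = numeric(),
               p_value = numeric(), significant = logical())
  rownames(pairwise) <- NULL
  list(results = results, anova_family = anova_family, pairwise = pairwise)
}
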
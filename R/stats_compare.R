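# Match/no-match contingency tables across model variants and Fisher's
# exact test computed from first principles (log-factorials, two-sided
# point-probability rule).

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (with relative tolerance 1e-7 on the comparison). Probabilities are
#' computed with log-factorials; no library statistics routine is called.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))` (rows: model-variant pair; columns: match
#'   vs no-match).
#' @param alternative Only `"two_sided"` is provided (the conventional
#'   two-sided rule).
#' @return The exact p-value in `(0, 1]`.
#' @export
fisher_exact <- function(table, alternative = "two_sided") {
  alternative <- match.arg(alternative, "two_sided")
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2, 2)) || any(tb < 0) || any(tb != round(tb)))
    stop("table must be a 2x2 matrix of non-negative integers")
  n <- sum(tb)
  if (n == 0) stop("undefined test: all-zero table")
  lf <- function(x) lgamma(x + 1)
  r1 <- tb[1, 1] + tb[1, 2]; r2 <- tb[2, 1] + tb[2, 2]
  c1 <- tb[1, 1] + tb[2, 1]
  k <- max(0, c1 - r2):min(r1, c1)
  # hypergeometric: C(r1,k) C(r2,c1-k) / C(n,c1)
  logp <- (lf(r1) - lf(k) - lf(r1 - k)) +
    (lf(r2) - lf(c1 - k) - lf(r2 - c1 + k)) -
    (lf(n) - lf(c1) - lf(n - c1))
  obs <- logp[k == tb[1, 1]]
  sum(exp(logp[logp <= obs + log1p(1e-7)]))
}

#' Collapse two groups of comparison states into a 2x2 match table
#'
#' Rows are the two groups, columns are match vs no-match counts
#' (`"no_vt"` entries are dropped). With groups = the ETS- and XTS-induced
#' VTs of one variant, 3/6 matches vs 2/7 matches gives
#' `rbind(c(3, 3), c(2, 5))`.
#'
#' @param states_a,states_b Character vectors with values `"match"`,
#'   `"no_match"` (anything else is dropped).
#' @return 2x2 integer matrix.
#' @export
match_table <- function(states_a, states_b) {
  cnt <- function(s) c(match = sum(s == "match"),
                       no_match = sum(s == "no_match"))
  rbind(a = cnt(states_a), b = cnt(states_b))
}

#' Build per-VT comparison summary and 2x2 tables across variant contrasts
#'
#' Takes the induction/comparison manifest of a full experiment and
#' produces, for each contrast of interest (baseline vs ab_tm, baseline vs
#' ab_only, baseline vs tm_only, ab_tm vs ab_only, ab_tm vs tm_only), a
#' per-VT state matrix with states `match` / `no_match` / `no_vt` for
#' inducibility, reentry pathway, and exit site, plus collapsed 2x2 tables
#' with their Fisher p-values. Pathway/exit tables have one row per
#' protocol mode (ETS vs XTS) when both are present, otherwise they
#' contrast the two variants of the pair; inducibility tables count
#' induced vs non-induced attempts per variant (rows = the variant pair).
#'
#' @param manifest Data frame with one row per (vt_id, variant, mode):
#'   `vt_id`, `variant`, `mode` (`"ETS"`/`"XTS"`), `induced` (logical),
#'   `pathway_match`, `exit_site_match` (logical, match vs the same
#'   `vt_id`'s circuit in the contrast's first variant; `NA` when no VT).
#' @param contrasts List of 2-element character vectors of variants.
#' @return Object of class `comparison_summary`: per contrast a list with
#'   `states` (per VT x mode), `tables`, `p_values`.
#' @export
build_match_matrix <- function(manifest,
                               contrasts = list(
                                 c("baseline", "ab_tm"),
                                 c("baseline", "ab_only"),
                                 c("baseline", "tm_only"),
                                 c("ab_tm", "ab_only"),
                                 c("ab_tm", "tm_only"))) {
  need <- c("vt_id", "variant", "mode", "induced", "pathway_match",
            "exit_site_match")
  stopifnot(all(need %in% names(manifest)))
  if (anyDuplicated(manifest[c("vt_id", "variant", "mode")]))
    stop("manifest error: duplicate VT identifiers")
  state_of <- function(rows, what) {
    ifelse(!rows$induced, "no_vt",
           ifelse(is.na(rows[[what]]), "no_vt",
                  ifelse(rows[[what]], "match", "no_match")))
  }
  out <- list()
  for (ct in contrasts) {
    a <- manifest[manifest$variant == ct[1], ]
    b <- manifest[manifest$variant == ct[2], ]
    states <- cbind(pathway = state_of(b, "pathway_match"),
                    exit_site = state_of(b, "exit_site_match"))
    rownames(states) <- paste(b$vt_id, b$mode, sep = ":")
    modes <- unique(b$mode)
    two_modes <- length(modes) >= 2
    mk <- function(what) {
      if (two_modes)
        match_table(state_of(b[b$mode == modes[1], ], what),
                    state_of(b[b$mode == modes[2], ], what))
      else
        match_table(state_of(a, what), state_of(b, what))
    }
    tabs <- list(
      inducibility = rbind(
        c(sum(a$induced %in% TRUE), sum(a$induced %in% FALSE)),
        c(sum(b$induced %in% TRUE), sum(b$induced %in% FALSE))),
      pathway = mk("pathway_match"),
      exit_site = mk("exit_site_match"))
    ps <- lapply(tabs, function(tb)
      if (sum(tb) > 0) fisher_exact(tb) else NA_real_)
    out[[paste(ct, collapse = "_vs_")]] <-
      list(states = states, tables = tabs, p_values = ps)
  }
  structure(out, class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    cnt <- apply(x[[nm]]$states, 2, function(s) table(factor(
      s, levels = c("match", "no_match", "no_vt"))))
    print(cnt)
    cat("Fisher p:", paste(names(x[[nm]]$p_values),
                           vapply(x[[nm]]$p_values, function(p)
                             ifelse(is.na(p), "NA", sprintf("%.4g", p)),
                             character(1)),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a comparison summary as CSV
#' @param summary A `comparison_summary`.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_comparison_csv <- function(summary, file) {
  rows <- do.call(rbind, lapply(names(summary), function(nm) {
    st <- summary[[nm]]$states
    data.frame(contrast = nm, vt_id = rownames(st),
               pathway = st[, "pathway"], exit_site = st[, "exit_site"],
               row.names = NULL)
  }))
  write.table(rows, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot a comparison summary as a colored state matrix
#'
#' Blue = consistent (match), red = not consistent, black = no VT induced,
#' one row per VT and one column per compared quantity.
#'
#' @param summary A `comparison_summary`.
#' @param contrast Name of the contrast to plot (default first).
#' @return A ggplot object (requires ggplot2).
#' @export
plot_comparison_matrix <- function(summary, contrast = names(summary)[1]) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  st <- summary[[contrast]]$states
  df <- data.frame(vt = rep(rownames(st), ncol(st)),
                   what = rep(colnames(st), each = nrow(st)),
                   state = as.vector(st))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$vt,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(match = "#2166ac",
                                          no_match = "#b2182b",
                                          no_vt = "#000000")) +
    ggplot2::labs(title = contrast, x = NULL, y = "VT") +
    ggplot2::theme_minimal()
}
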
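# Exhaustive Pearson correlation screen across the variable families,
# significance filtering, strength classification and N-vs-D t-tests.

#' Pearson correlation with coefficient of determination
#'
#' Sample Pearson r on pairwise-complete observations, with the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; missing values removed
#'   pairwise.
#' @return List `r`, `r2`, `p`, `n`, `flag` (`"ok"`, `"insufficient"` for
#'   n < 3, `"degenerate"` for zero variance; statistics `NA` when flagged).
#' @export
pearson_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = n,
                flag = "insufficient"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = n,
                flag = "degenerate"))
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value, n = n, flag = "ok")
}

#' Classify correlation strength from R-squared
#'
#' Weak up to 0.30, moderate above 0.30 and up to 0.70, strong above 0.70.
#'
#' @param r2 Numeric vector of coefficients of determination in `[0, 1]`
#'   (`NA` allowed, propagated).
#' @return Character vector: `"weak"`, `"moderate"` or `"strong"`.
#' @export
classify_strength <- function(r2) {
  if (any(!is.na(r2) & (r2 < 0 | r2 > 1)))
    stop("r2 must lie in [0, 1]")
  ifelse(is.na(r2), NA_character_,
         ifelse(r2 <= 0.30, "weak",
                ifelse(r2 <= 0.70, "moderate", "strong")))
}

# the full pair design: 84 x 18 inter pairs, C(84,2) intra-3D, C(12,2)
# intra-LOAD
correlation_pairs <- function() {
  reg <- variable_registry()
  other <- c(reg$load, reg$func, reg$biol, reg$clin)
  inter <- expand.grid(var_a = reg$threeD, var_b = other,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i3 <- t(utils::combn(reg$threeD, 2))
  il <- t(utils::combn(reg$load, 2))
  rbind(cbind(inter, category = "inter"),
        data.frame(var_a = i3[, 1], var_b = i3[, 2], category = "intra3D"),
        data.frame(var_a = il[, 1], var_b = il[, 2], category = "intraLOAD"))
}

#' Run the exhaustive correlation design for one patient group
#'
#' Evaluates every 3D-versus-{LOAD, FUNC, BIOL, CLIN} pair (84 x 18 = 1512
#' inter-variable correlations), every pair within the 3D variables
#' (C(84,2) = 3486) and within the LOAD variables (C(12,2) = 66), with
#' pairwise-complete deletion, the p < alpha significance screen (no
#' multiple-testing correction by default, Benjamini-Hochberg optional) and
#' the weak/moderate/strong classification.
#'
#' @param table Variable table: data.frame with a `group` column and the
#'   102 analysis variables of [variable_registry()].
#' @param group `"ALL"` (every row) or a group label present in the table.
#' @param alpha Significance level for the screen.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per pair: `var_a`, `var_b`, `category`,
#'   `group`, `n`, `r`, `r2`, `p`, `significant`, `strength`, `flag`.
#' @export
correlate_all <- function(table, group = "ALL", alpha = 0.05,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  rows <- if (identical(group, "ALL")) rep(TRUE, nrow(table)) else
    table$group == group
  if (!any(rows)) stop("no patients in group ", group)
  sub <- table[rows, , drop = FALSE]
  reg <- variable_registry()
  miss <- setdiff(unlist(reg), names(sub))
  if (length(miss)) stop("variable table lacks columns: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  pairs <- correlation_pairs()
  res <- mapply(function(va, vb) pearson_r2(sub[[va]], sub[[vb]]),
                pairs$var_a, pairs$var_b, SIMPLIFY = FALSE)
  out <- data.frame(
    var_a = pairs$var_a, var_b = pairs$var_b, category = pairs$category,
    group = group,
    n = vapply(res, `[[`, 0L, "n"),
    r = vapply(res, `[[`, 0, "r"),
    r2 = vapply(res, `[[`, 0, "r2"),
    p = vapply(res, `[[`, 0, "p"),
    flag = vapply(res, `[[`, "", "flag"),
    row.names = NULL)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out$strength <- classify_strength(out$r2)
  out
}

#' Equal-variance Student's t-test between two patient groups
#'
#' @param table Variable table as in [correlate_all()].
#' @param var Variable name to compare.
#' @param groups Two group labels (default N vs D).
#' @param welch Use the Welch unequal-variance form instead.
#' @return List `t`, `p`, `df`, `n` (per group), `flag` (`"ok"` or
#'   `"insufficient"`).
#' @export
group_ttest <- function(table, var, groups = c("N", "D"), welch = FALSE) {
  x <- table[[var]][table$group == groups[1]]
  y <- table[[var]][table$group == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L ||
      (stats::sd(x) == 0 && stats::sd(y) == 0 && !welch))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n = c(length(x), length(y)), flag = "insufficient"))
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = c(length(x), length(y)), flag = "ok")
}

#' Summarise a correlation screen by 3D-variable family
#'
#' For each family of 3D variables (angles per projection plane, forefoot
#' heights, midfoot heights) counts the pairs against the 12 LOAD variables
#' (15 x 12 = 180 per angle family, 20 x 12 = 240 forefoot heights,
#' 4 x 12 = 48 midfoot heights) and how many are significant; also reports
#' the median and quartiles of the significant inter-variable R-squared.
#'
#' @param results Output of [correlate_all()] (one or more groups,
#'   row-bound).
#' @return List `families` (data.frame: group, family, n_pairs, n_sig,
#'   pct_sig) and `r2_significant` (data.frame: group, n_sig, median, q1,
#'   q3 of significant inter R-squared).
#' @export
summarize_correlations <- function(results) {
  fams <- variable_families_3d()
  loads <- variable_names_load()
  fam_rows <- list()
  for (g in unique(results$group)) {
    rg <- results[results$group == g & results$category == "inter" &
                    results$var_b %in% loads, ]
    for (f in names(fams)) {
      rf <- rg[rg$var_a %in% fams[[f]], ]
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        group = g, family = f, n_pairs = nrow(rf),
        n_sig = sum(rf$significant),
        pct_sig = if (nrow(rf)) 100 * mean(rf$significant) else NA_real_)
    }
  }
  r2_rows <- lapply(unique(results$group), function(g) {
    ri <- results[results$group == g & results$category == "inter" &
                    results$significant, ]
    q <- if (nrow(ri)) stats::quantile(ri$r2, c(0.25, 0.5, 0.75)) else
      rep(NA_real_, 3)
    data.frame(group = g, n_sig = nrow(ri), median_r2 = q[[2]],
               q1_r2 = q[[1]], q3_r2 = q[[3]])
  })
  list(families = do.call(rbind, fam_rows),
       r2_significant = do.call(rbind, r2_rows))
}
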
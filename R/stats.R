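#' Variance components and repeatability for a balanced trial stratum
#'
#' Method-of-moments ANOVA estimator for a balanced two-way layout
#' (g genotypes x r blocks, one observation per cell) with block as fixed
#' and genotype as random effect: the residual variance is the residual
#' mean square of the additive two-way ANOVA, the genotypic variance is
#' `(MS_genotype - MS_residual) / r` (clamped at zero), and the
#' repeatability is
#' `h2 = sigma2_gen / (sigma2_gen + sigma2_eps / r)`.
#' For balanced data this coincides in expectation with the REML
#' mixed-model estimate; unbalanced layouts are rejected.
#'
#' @param table Long trait table (see [seasonal_table()]) with columns
#'   `genotype`, `block`, `rows`, `campaign_id`, `trait`, `value`.
#' @param trait,campaign Stratum selectors.
#' @param rows_per_plot Plot size (row count) selecting the stratum;
#'   `NULL` if the table has no `rows` column or a single stratum.
#' @return List of class `variance_components`: `sigma2_gen`,
#'   `sigma2_eps`, `n_genotypes`, `n_blocks`, `h2`.
#' @export
estimate_components <- function(table, trait = NULL, campaign = NULL,
                                rows_per_plot = NULL) {
  d <- table
  if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
  if (!is.null(campaign)) d <- d[d$campaign_id == campaign, , drop = FALSE]
  if (!is.null(rows_per_plot)) d <- d[d$rows == rows_per_plot, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (!nrow(d)) stop("no observations in the requested stratum", call. = FALSE)
  g <- length(unique(d$genotype)); r <- length(unique(d$block))
  tab <- table(d$genotype, d$block)
  if (any(tab != 1))
    stop(paste("unbalanced genotype x block layout: this estimator requires",
               "exactly one observation per cell; fit a general mixed model",
               "instead"), call. = FALSE)
  if (g < 2 || r < 2)
    stop("need at least 2 genotypes and 2 blocks", call. = FALSE)
  y <- d$value
  gm <- tapply(y, d$genotype, mean)
  bm <- tapply(y, d$block, mean)
  mu <- mean(y)
  ss_gen <- r * sum((gm - mu)^2)
  ss_block <- g * sum((bm - mu)^2)
  ss_tot <- sum((y - mu)^2)
  ss_res <- ss_tot - ss_gen - ss_block
  ms_gen <- ss_gen / (g - 1)
  ms_res <- max(0, ss_res) / ((g - 1) * (r - 1))
  sigma2_eps <- ms_res
  sigma2_gen <- max(0, (ms_gen - ms_res) / r)
  h2 <- if (sigma2_gen + sigma2_eps / r > 0)
    sigma2_gen / (sigma2_gen + sigma2_eps / r) else 0
  structure(list(sigma2_gen = sigma2_gen, sigma2_eps = sigma2_eps,
                 n_genotypes = g, n_blocks = r, h2 = h2),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma2_gen %.4g, sigma2_eps %.4g (g=%d, r=%d), h2 = %.3f\n",
    x$sigma2_gen, x$sigma2_eps, x$n_genotypes, x$n_blocks, x$h2))
  invisible(x)
}

#' Repeatability profile by campaign and plot size
#'
#' Runs [estimate_components()] for every campaign x rows-per-plot
#' stratum of one trait, producing the table behind repeatability-vs-plot-
#' size figures. Strata that fail (missing or unbalanced) are omitted with
#' a warning.
#'
#' @param table Long trait table.
#' @param trait Trait name.
#' @return Data frame: `campaign_id`, `tt`, `rows`, `h2`, `sigma2_gen`,
#'   `sigma2_eps`.
#' @export
repeatability_profile <- function(table, trait) {
  d <- table[table$trait == trait & is.finite(table$value), , drop = FALSE]
  if (!nrow(d)) {
    warning(sprintf("trait '%s' absent from table", trait))
    return(data.frame(campaign_id = character(0), tt = numeric(0),
                      rows = integer(0), h2 = numeric(0),
                      sigma2_gen = numeric(0), sigma2_eps = numeric(0)))
  }
  strata <- unique(d[, c("campaign_id", "tt", "rows")])
  strata <- strata[order(strata$tt, strata$rows), , drop = FALSE]
  res <- lapply(seq_len(nrow(strata)), function(i) {
    vc <- tryCatch(
      estimate_components(d, trait = trait,
                          campaign = strata$campaign_id[i],
                          rows_per_plot = strata$rows[i]),
      error = function(e) {
        warning(sprintf("stratum %s / %d rows omitted: %s",
                        strata$campaign_id[i], strata$rows[i],
                        conditionMessage(e)))
        NULL
      })
    if (is.null(vc)) return(NULL)
    data.frame(campaign_id = strata$campaign_id[i], tt = strata$tt[i],
               rows = strata$rows[i], h2 = vc$h2,
               sigma2_gen = vc$sigma2_gen, sigma2_eps = vc$sigma2_eps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

#' Pearson correlation with significance codes
#'
#' Pearson product-moment correlation of paired series, with the two-sided
#' p-value from the t-distribution on n - 2 degrees of freedom and the
#' conventional star codes: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param x,y Numeric vectors; pairs with a missing member are dropped.
#' @return List with `r`, `p`, `n`, `code`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  code <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(r = unname(ct$estimate), p = p, n = n, code = code)
}

#' Correlation matrix with significance codes
#'
#' Pairwise [correlate()] over the columns of a data frame, formatted the
#' way trial reports print them (`"0.75 ***"`).
#'
#' @param df Data frame of numeric columns, rows paired by
#'   (genotype, block).
#' @return List with numeric matrices `r`, `p` and character matrix
#'   `formatted`.
#' @export
correlation_matrix <- function(df) {
  nm <- names(df)
  k <- length(nm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  f <- matrix("", k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; f[i, j] <- "1"; next }
    res <- tryCatch(correlate(df[[i]], df[[j]]), error = function(e) NULL)
    if (is.null(res)) next
    r[i, j] <- res$r; p[i, j] <- res$p
    f[i, j] <- sprintf("%.2f %s", res$r, res$code)
  }
  list(r = r, p = p, formatted = f)
}

#' Tukey HSD genotype comparison
#'
#' Genotype means for one trait/campaign stratum with the honest
#' significant difference at level `alpha`:
#' `HSD = q(1 - alpha, g, df_err) * sqrt(MS_err / r)`, `MS_err` the
#' residual mean square of the additive genotype + block ANOVA and `r` the
#' number of blocks. Genotype pairs whose means differ by more than the
#' HSD are declared different; a compact letter display summarizes the
#' grouping (genotypes sharing a letter are not distinguishable).
#'
#' @param table Long trait table.
#' @param trait,campaign,rows_per_plot Stratum selectors (see
#'   [estimate_components()]).
#' @param alpha Familywise error level (default 0.05).
#' @return List with `means` (data frame `genotype`, `mean`, `group`),
#'   `hsd`, `ms_err`, `df_err`, `alpha`.
#' @export
hsd_compare <- function(table, trait = NULL, campaign = NULL,
                        rows_per_plot = NULL, alpha = 0.05) {
  d <- table
  if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
  if (!is.null(campaign)) d <- d[d$campaign_id == campaign, , drop = FALSE]
  if (!is.null(rows_per_plot)) d <- d[d$rows == rows_per_plot, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  g <- length(unique(d$genotype)); r <- length(unique(d$block))
  if (r < 2) stop("insufficient replication: need >= 2 blocks", call. = FALSE)
  if (any(table(d$genotype, d$block) != 1))
    stop("unbalanced genotype x block layout", call. = FALSE)
  y <- d$value
  gm <- tapply(y, d$genotype, mean)
  bm <- tapply(y, d$block, mean)
  mu <- mean(y)
  ss_res <- sum((y - mu)^2) - r * sum((gm - mu)^2) - g * sum((bm - mu)^2)
  df_err <- (g - 1) * (r - 1)
  ms_err <- max(0, ss_res) / df_err
  hsd <- stats::qtukey(1 - alpha, g, df_err) * sqrt(ms_err / r)
  means <- sort(gm, decreasing = TRUE)
  groups <- compact_letters(means, hsd)
  list(means = data.frame(genotype = names(means), mean = as.numeric(means),
                          group = groups, stringsAsFactors = FALSE),
       hsd = hsd, ms_err = ms_err, df_err = df_err, alpha = alpha)
}

# compact letter display for means sorted in decreasing order: maximal
# runs of means spanning <= hsd get one letter each, nested runs absorbed
compact_letters <- function(means, hsd) {
  k <- length(means)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && means[i] - means[j + 1] <= hsd + 1e-12) j <- j + 1
    runs[[length(runs) + 1L]] <- c(i, j)
  }
  # drop runs contained in an earlier (longer) run
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs)) {
    if (a != b && keep[b] &&
        runs[[a]][1] <= runs[[b]][1] && runs[[a]][2] >= runs[[b]][2] &&
        !(runs[[a]][1] == runs[[b]][1] && runs[[a]][2] == runs[[b]][2] && a > b))
      keep[b] <- FALSE
  }
  runs <- runs[keep]
  lab <- rep("", k)
  for (s in seq_along(runs)) {
    rng <- runs[[s]][1]:runs[[s]][2]
    lab[rng] <- paste0(lab[rng], letters[(s - 1) %% 26 + 1])
  }
  lab
}
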
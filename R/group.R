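## Group-level analysis of coupling maps: site harmonization, covariate
## residualization, Mann-Whitney comparisons at global / regional / network
## level with BH-FDR control per family, and symptom partial correlations
## for the networks that survive correction.

coupling_matrix <- function(coupling) {
  if (is.matrix(coupling)) {
    if (is.null(rownames(coupling))) stop_mfc("coupling matrix needs subject rownames")
    return(coupling)
  }
  if (is.data.frame(coupling)) {
    need <- c("subject_id", "region", "value")
    if (!all(need %in% names(coupling)))
      stop_mfc("long coupling table needs columns: ", paste(need, collapse = ", "))
    wide <- stats::xtabs(value ~ subject_id + region, data = coupling)
    m <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                dimnames = dimnames(wide))
    return(m)
  }
  stop_mfc("coupling must be a subjects x regions matrix or a long table")
}

#' Group comparison of morphology-function coupling
#'
#' The full inferential sequence for a cohort of regional coupling maps:
#' site effects are removed by [combat_harmonize()] (group and covariates
#' protected), the covariates are regressed out of every feature (pooled
#' across groups, group excluded from the design), case and control subjects
#' are compared by Mann-Whitney tests at the global, regional, and network
#' level, p-values are BH-FDR corrected within each family (regions;
#' networks), and for every network significant at the chosen threshold the
#' case-group network coupling is partially correlated with the symptom
#' score (adjusting for `symptom_covariates`), again FDR-corrected.
#'
#' @param coupling Subjects x regions matrix of regional coupling values
#'   (rownames = subject ids), or a long data frame with columns
#'   `subject_id`, `region`, `value`.
#' @param cohort Data frame with columns `subject_id`, `group`
#'   (`"case"` / `"control"`), `site`, the covariates, and `symptom_score`
#'   (cases; may be missing for controls).
#' @param partition Region-to-network partition (see [network_coupling()]).
#' @param covariates Covariate column names used for harmonization and
#'   residualization.
#' @param symptom_covariates Covariate column names for the symptom partial
#'   correlations.
#' @param global_values Optional named per-subject vector of global coupling
#'   values; defaults to the row means of the (harmonized, residualized)
#'   regional features.
#' @param fdr_threshold Significance threshold on the q-values.
#' @param harmonize Set to `FALSE` to skip site harmonization (single-site
#'   cohorts skip it automatically).
#' @return Object of class `mfc_group` with elements `regional`, `network`,
#'   `global`, `symptom`, `features` (harmonized residualized matrix), and
#'   metadata.
#' @export
mfc_group_analysis <- function(coupling, cohort, partition,
                               covariates = c("age", "sex", "education", "mean_fd"),
                               symptom_covariates = c("age", "sex", "education"),
                               global_values = NULL,
                               fdr_threshold = 0.05,
                               harmonize = TRUE) {
  feats <- coupling_matrix(coupling)
  if (!all(c("subject_id", "group", "site") %in% names(cohort)))
    stop_mfc("cohort needs columns subject_id, group, site")
  if (!all(rownames(feats) %in% cohort$subject_id))
    stop_mfc("subjects in coupling but not in cohort table")
  cohort <- cohort[match(rownames(feats), cohort$subject_id), ]
  if (!all(cohort$group %in% c("case", "control")))
    stop_mfc("group must be 'case' or 'control'")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_mfc("fdr_threshold must lie in (0, 1)")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop_mfc("missing covariate columns: ", paste(miss, collapse = ", "))

  is_case <- cohort$group == "case"
  cov_df <- cohort[, covariates, drop = FALSE]

  ## 1. harmonization (site as batch, group + covariates protected)
  if (harmonize && length(unique(cohort$site)) > 1L) {
    protect <- cbind(design_matrix(data.frame(group = cohort$group)),
                     design_matrix(cov_df))
    feats <- combat_harmonize(feats, cohort$site, protect)
  }

  ## 2. covariate residualization, pooled, group excluded from the design
  resid_feats <- apply(feats, 2L, residualize, covariates = cov_df)
  rownames(resid_feats) <- rownames(feats)

  ## 3. per-region tests
  test_units <- function(mat) {
    res <- lapply(seq_len(ncol(mat)), function(j)
      mann_whitney(mat[is_case, j], mat[!is_case, j]))
    data.frame(
      unit = colnames(mat),
      z = vapply(res, `[[`, 0, "z"),
      p = vapply(res, `[[`, 0, "p"),
      direction = ifelse(vapply(res, `[[`, 0, "z") >= 0, "case>control", "case<control"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  regional <- test_units(resid_feats)
  regional$q <- bh_fdr(regional$p)
  regional <- regional[, c("unit", "z", "p", "q", "direction")]

  ## network-level features: per-subject mean coupling within network
  labs <- colnames(resid_feats)
  pmap <- as_partition(partition, labs)
  nets <- unique(pmap)
  net_feats <- vapply(nets, function(nw)
    rowMeans(resid_feats[, pmap == nw, drop = FALSE]), numeric(nrow(resid_feats)))
  colnames(net_feats) <- nets
  network <- test_units(net_feats)
  network$q <- bh_fdr(network$p)
  network <- network[, c("unit", "z", "p", "q", "direction")]

  ## global test
  if (is.null(global_values)) {
    gv <- rowMeans(resid_feats)
    global_source <- "mean of regional features"
  } else {
    gv <- residualize(global_values[rownames(feats)], cov_df)
    global_source <- "supplied global coupling"
  }
  gt <- mann_whitney(gv[is_case], gv[!is_case])
  global <- data.frame(unit = "global", z = gt$z, p = gt$p,
                       direction = ifelse(gt$z >= 0, "case>control", "case<control"),
                       source = global_source, stringsAsFactors = FALSE)

  ## 4. symptom partial correlations for significant networks (cases only)
  sig_nets <- network$unit[network$q < fdr_threshold]
  symptom <- NULL
  if (length(sig_nets) && "symptom_score" %in% names(cohort)) {
    sc <- cohort$symptom_score
    usable <- is_case & !is.na(sc)
    k <- length(symptom_covariates)
    if (sum(usable) > k + 3L) {
      zdf <- cohort[usable, symptom_covariates, drop = FALSE]
      rows <- lapply(sig_nets, function(nw) {
        pc <- tryCatch(partial_correlation(net_feats[usable, nw], sc[usable], zdf),
                       mfc_degenerate_error = function(e) NULL)
        if (is.null(pc)) return(NULL)
        data.frame(network = nw, r = pc$r, df = pc$df, p = pc$p,
                   stringsAsFactors = FALSE)
      })
      symptom <- do.call(rbind, rows)
      if (!is.null(symptom)) symptom$q <- bh_fdr(symptom$p)
    }
  }

  structure(list(
    regional = regional, network = network, global = global, symptom = symptom,
    features = resid_feats, n_case = sum(is_case), n_control = sum(!is_case),
    covariates = covariates, fdr_threshold = fdr_threshold,
    harmonized = harmonize && length(unique(cohort$site)) > 1L
  ), class = "mfc_group")
}

#' @export
print.mfc_group <- function(x, ...) {
  cat("Morphology-function coupling group comparison\n")
  cat("  subjects:", x$n_case, "cases /", x$n_control, "controls;",
      nrow(x$regional), "regions,", nrow(x$network), "networks",
      if (x$harmonized) "(site-harmonized)" else "(single site)", "\n")
  cat("  global: z =", format(x$global$z, digits = 4),
      ", p =", format(x$global$p, digits = 4),
      paste0("(", x$global$direction, ")"), "\n")
  nsig_r <- sum(x$regional$q < x$fdr_threshold)
  nsig_n <- sum(x$network$q < x$fdr_threshold)
  cat("  significant at q <", x$fdr_threshold, ":", nsig_r, "regions,",
      nsig_n, "networks\n")
  if (!is.null(x$symptom)) {
    cat("  symptom correlations (cases, partial):\n")
    for (i in seq_len(nrow(x$symptom)))
      cat(sprintf("    %s: r = %.3f, q = %.4f\n", x$symptom$network[i],
                  x$symptom$r[i], x$symptom$q[i]))
  }
  invisible(x)
}

#' @export
summary.mfc_group <- function(object, ...) {
  out <- list(
    network = object$network,
    top_regions = object$regional[order(object$regional$p), ][
      seq_len(min(10L, nrow(object$regional))), ],
    global = object$global,
    symptom = object$symptom
  )
  class(out) <- "summary.mfc_group"
  out
}

#' @export
print.summary.mfc_group <- function(x, ...) {
  cat("Network-level comparison:\n")
  print(x$network, row.names = FALSE, digits = 4)
  cat("\nStrongest regional differences:\n")
  print(x$top_regions, row.names = FALSE, digits = 4)
  cat("\nGlobal:\n")
  print(x$global, row.names = FALSE, digits = 4)
  if (!is.null(x$symptom)) {
    cat("\nSymptom partial correlations:\n")
    print(x$symptom, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.mfc_group <- function(x, ...) {
  z <- x$regional$z
  graphics::barplot(sort(z), border = NA,
                    col = ifelse(sort(z) >= 0, "firebrick", "steelblue"),
                    ylab = "Mann-Whitney z (case - control)",
                    xlab = "regions (sorted)",
                    main = "Regional coupling differences", ...)
  graphics::abline(h = 0)
  invisible(x)
}
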
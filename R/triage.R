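#' Pairwise Spearman rank correlations
#'
#' Spearman correlation for every column pair, computed on pairwise-complete
#' rows with ties mid-ranked. Entries backed by fewer than 3 complete pairs
#' are `NA`.
#'
#' @param a data frame of numeric columns.
#' @param b optional second data frame with paired rows (same
#'   observations); when omitted, correlations are within `a`.
#' @return A correlation matrix (rows = columns of `a`, cols = columns of
#'   `b` or `a`).
#' @export
pairwise_spearman <- function(a, b = NULL) {
  a <- as.data.frame(a)
  bb <- if (is.null(b)) a else as.data.frame(b)
  if (!is.null(b) && nrow(a) != nrow(bb)) {
    abort("`a` and `b` must have paired rows.")
  }
  rho <- suppressWarnings(
    cor(a, bb, method = "spearman", use = "pairwise.complete.obs")
  )
  counts <- crossprod(!is.na(as.matrix(a)), !is.na(as.matrix(bb)))
  rho[counts < 3] <- NA_real_
  rho
}

#' Variance-inflation (multicollinearity) indices
#'
#' For each feature `j`, the index is `VIF_j = 1 / (1 - R^2_j)` where
#' `R^2_j` is from the least-squares regression (with intercept) of feature
#' `j` on all other features, fitted on complete rows. Perfect collinearity
#' yields `Inf` with `collinear = TRUE`.
#'
#' @param table data frame of numeric feature columns (>= 2).
#' @return A tibble `(feature, vif, r_squared, collinear)`.
#' @export
multicollinearity <- function(table) {
  df <- as.data.frame(table)
  if (ncol(df) < 2) abort("Need at least 2 features for multicollinearity.")
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 2) {
    abort("Need at least p + 2 complete rows for p features.")
  }
  purrr::map_dfr(names(df), function(j) {
    fml <- as.formula(paste0("`", j, "` ~ ."))
    r2 <- suppressWarnings(summary(lm(fml, data = df))$r.squared)
    # guard against numerically perfect fits
    collinear <- r2 >= 1 - 1e-12
    tibble(
      feature = j,
      vif = if (collinear) Inf else 1 / (1 - r2),
      r_squared = r2,
      collinear = collinear
    )
  })
}

#' Agglomerative similarity clustering of features
#'
#' Features are clustered with average linkage on the distance
#' `1 - |rho_spearman|`, so perfectly (anti)correlated features merge at
#' height 0 and unrelated features near height 1.
#'
#' @param table data frame of numeric feature columns (>= 2).
#' @return A list with `hclust` (the stats::hclust object) and `linkage`
#'   (tibble `step`, `merge1`, `merge2`, `height`; negative indices are
#'   leaves, positive are prior merge steps).
#' @export
similarity_clusters <- function(table) {
  df <- as.data.frame(table)
  if (ncol(df) < 2) abort("Need at least 2 features to cluster.")
  rho <- pairwise_spearman(df)
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  hc <- hclust(as.dist(d), method = "average")
  list(
    hclust = hc,
    linkage = tibble(
      step = seq_len(nrow(hc$merge)),
      merge1 = hc$merge[, 1],
      merge2 = hc$merge[, 2],
      height = hc$height
    )
  )
}

#' Triage redundant features
#'
#' Three elimination passes, mirroring interactive feature selection with a
#' deterministic rule set:
#' 1. *Correlation*: scanning columns left to right, a feature is dropped
#'    when its absolute Spearman correlation with an earlier retained
#'    feature exceeds `r_max` (the later column of the pair is dropped).
#' 2. *Multicollinearity*: iteratively drop the feature with the largest
#'    variance-inflation index until all indices are `<= vif_max`.
#' 3. *Manual*: `manual_drops` (the stand-in for visual-inspection
#'    elimination) are removed last.
#'
#' Every elimination is recorded with a machine-readable reason. The output
#' is deterministic given the table and thresholds.
#'
#' @param table data frame of numeric feature columns.
#' @param r_max absolute-correlation threshold (default 0.8).
#' @param vif_max multicollinearity-index threshold (default 5).
#' @param manual_drops character vector of features to drop manually.
#' @return A list of class `triage_report`: `retained` (character),
#'   `eliminated` (tibble `feature`, `reason`, `detail`), `spearman`
#'   (correlation matrix of the input), `vif` (final indices of retained
#'   features), `linkage` (similarity clustering of the input).
#' @export
select_features <- function(table, r_max = 0.8, vif_max = 5,
                            manual_drops = character()) {
  df <- as.data.frame(table)
  if (!all(purrr::map_lgl(df, is.numeric))) {
    abort("select_features() expects numeric feature columns only.")
  }
  rho <- pairwise_spearman(df)
  clusters <- similarity_clusters(df)
  eliminated <- tibble(feature = character(), reason = character(),
                       detail = character())

  # pass 1: pairwise correlation, drop the later column
  retained <- character()
  for (j in names(df)) {
    too_cor <- retained[!is.na(rho[retained, j]) & abs(rho[retained, j]) > r_max]
    if (length(too_cor) > 0) {
      eliminated <- bind_rows(eliminated, tibble(
        feature = j, reason = "correlation",
        detail = sprintf("|rho|=%.3f with %s", abs(rho[too_cor[1], j]), too_cor[1])
      ))
    } else {
      retained <- c(retained, j)
    }
  }

  # pass 2: iterative VIF elimination
  while (length(retained) >= 2) {
    if (sum(complete.cases(df[retained])) < length(retained) + 2) {
      warn("Too few complete rows for multicollinearity screening; skipped.")
      break
    }
    vif <- multicollinearity(df[retained])
    worst <- vif %>% arrange(dplyr::desc(.data$vif)) %>% slice(1)
    if (worst$vif <= vif_max) break
    eliminated <- bind_rows(eliminated, tibble(
      feature = worst$feature, reason = "multicollinearity",
      detail = sprintf("VIF=%s", format(worst$vif, digits = 4))
    ))
    retained <- setdiff(retained, worst$feature)
  }

  # pass 3: manual drops
  manual <- intersect(manual_drops, retained)
  if (length(manual) > 0) {
    eliminated <- bind_rows(eliminated, tibble(
      feature = manual, reason = "manual", detail = "requested drop"
    ))
    retained <- setdiff(retained, manual)
  }

  if (length(retained) == 0) {
    abort("All features were eliminated; relax r_max/vif_max or manual_drops.")
  }
  vif_ok <- length(retained) >= 2 &&
    sum(complete.cases(df[retained])) >= length(retained) + 2
  vif_final <- if (vif_ok) multicollinearity(df[retained]) else
    tibble(feature = retained, vif = NA_real_, r_squared = NA_real_,
           collinear = FALSE)
  structure(
    list(
      retained = retained, eliminated = eliminated,
      spearman = rho, vif = vif_final, linkage = clusters
    ),
    class = "triage_report"
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf(
    "<triage_report> %d retained, %d eliminated\n",
    length(x$retained), nrow(x$eliminated)
  ))
  if (nrow(x$eliminated) > 0) print(x$eliminated)
  invisible(x)
}

#' Plot a triage correlation heatmap
#'
#' @param object a `triage_report` from [select_features()].
#' @param ... unused.
#' @return A ggplot heatmap of the Spearman matrix, eliminated features
#'   marked.
#' @export
autoplot.triage_report <- function(object, ...) {
  rho <- object$spearman
  long <- as_tibble(rho, rownames = "f1") %>%
    tidyr::pivot_longer(-"f1", names_to = "f2", values_to = "rho") %>%
    mutate(
      f1 = factor(.data$f1, levels = rownames(rho)),
      f2 = factor(.data$f2, levels = rownames(rho))
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$f1, .data$f2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman ρ") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Feature correlation heatmap",
      subtitle = sprintf(
        "retained: %s", paste(object$retained, collapse = ", ")
      )
    )
}
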
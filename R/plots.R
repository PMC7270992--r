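#' Ward-clustered heatmap of associated metabolites
#'
#' Renders the residualized metabolite-by-sample matrix as a heatmap with
#' both axes ordered by Ward clustering ([wardCluster()]), annotated with
#' genotype group / cohort and lipid-class colour bars. Setting
#' `excludeClass = "TAG"` reproduces the exploratory view without the
#' on-target class, which sharpens carrier/non-carrier separation when the
#' primary-target signal dominates.
#'
#' @param x a preprocessed [MetaboExperiment-class] with an `"rnt"` assay.
#' @param metabolites output of [dedupAnnotations()], typically restricted
#'   to associated metabolites.
#' @param sampleIds analysis samples (default: fasting study samples).
#' @param excludeClass optional lipid class(es) to leave out.
#' @param file optional path (png/pdf inferred from extension); `NULL` plots
#'   to the active device.
#' @return Invisibly, the list from [wardCluster()] for the plotted matrix.
#' @export
plotAssociationHeatmap <- function(x, metabolites, sampleIds = NULL,
                                   excludeClass = NULL, file = NULL) {
    stopifnot(is(x, "MetaboExperiment"))
    if (!is.null(excludeClass))
        metabolites <- metabolites[!(metabolites$lipid_class %in%
                                     excludeClass), , drop = FALSE]
    R <- residualMatrix(x, metabolites, sampleIds)
    cl <- wardCluster(R)
    sd <- colData(x)[colnames(R), , drop = FALSE]
    annCol <- data.frame(
        group = paste(sd$cohort, sd$genotype, sep = "/"),
        row.names = colnames(R))
    key <- ifelse(is.na(metabolites$metabolite), metabolites$feature,
                  metabolites$metabolite)
    cls <- metabolites$lipid_class[match(rownames(R), key)]
    cls[is.na(cls)] <- "other"
    annRow <- data.frame(class = cls, row.names = rownames(R))
    ph <- pheatmap::pheatmap(
        R,
        cluster_rows = cl$rowHclust, cluster_cols = cl$colHclust,
        annotation_col = annCol, annotation_row = annRow,
        show_colnames = FALSE, show_rownames = nrow(R) <= 60,
        fontsize_row = 6, silent = !is.null(file),
        filename = if (is.null(file)) NA else file)
    invisible(cl)
}

#' Effect sizes by m/z per lipid class
#'
#' Scatter of the per-metabolite genotype effect (beta, in SD units of the
#' transformed abundance) against mass-to-charge ratio, faceted/coloured by
#' lipid class — the view in which size-related effect gradients within a
#' class (e.g. ceramides) become visible.
#'
#' @param metabolites output of [dedupAnnotations()] for one dataset.
#' @param featureData feature metadata carrying `mz` (e.g. [featureMeta()]).
#' @param file optional output path for [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when written to file.
#' @export
plotEffectByMz <- function(metabolites, featureData, file = NULL) {
    fd <- as.data.frame(featureData)
    df <- data.frame(
        mz = fd[metabolites$feature, "mz"],
        beta = metabolites$beta,
        class = ifelse(is.na(metabolites$lipid_class), "other",
                       metabolites$lipid_class),
        stringsAsFactors = FALSE)
    df <- df[!is.na(df$beta), , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$beta,
                                          colour = .data$class)) +
        ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                            colour = "grey50") +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::labs(x = "mass-to-charge ratio (m/z)",
                      y = "effect of carrier allele (SD units)",
                      colour = "metabolite class") +
        ggplot2::theme_minimal()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 7, height = 4.5, dpi = 150)
        return(invisible(p))
    }
    p
}
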
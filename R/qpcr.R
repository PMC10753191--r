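#' Myosin heavy chain target and reference gene sets
#'
#' Targets are the six MHC isoform genes (MYH7/MHC1beta slow; MYH2/MHC2A,
#' MYH1/MHC2X, MYH4/MHC2B fast; MYH3/MHCemb and MYH8/MHCneo regenerative);
#' references are the three stable muscle reference genes used for
#' normalisation.
#'
#' @return Character vector of gene symbols.
#' @export
mhc_genes <- function() c("MYH7", "MYH2", "MYH1", "MYH4", "MYH3", "MYH8")

#' @rdname mhc_genes
#' @export
mhc_nonregenerative_genes <- function() c("MYH7", "MYH2", "MYH1", "MYH4")

#' @rdname mhc_genes
#' @export
reference_genes <- function() c("HPRT1", "RPL13A", "SDHA")

#' Collapse technical qPCR replicates
#'
#' Arithmetic mean Cq per (sample, gene); pairs whose replicate sd exceeds
#' 0.5 cycles are flagged for review, not dropped.
#'
#' @param table Long Cq tibble (see [read_qpcr()]).
#' @return Tibble `sample_id`, `genotype`, `gene`, `Cq`, `n_replicates`,
#'   `high_replicate_sd`.
#' @export
collapse_replicates <- function(table) {
  table |>
    dplyr::group_by(.data$sample_id, .data$genotype, .data$gene) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     high_replicate_sd = dplyr::n() > 1 && sd(.data$Cq) > 0.5,
                     Cq = mean(.data$Cq),
                     .groups = "drop")
}

#' Reference-normalised relative quantity (log10)
#'
#' `RQ = 2^-(Cq_target - mean(Cq_references))`, assuming amplification
#' efficiency 2 (no efficiencies are estimated); the arithmetic mean of the
#' reference Cq values is equivalent to the geometric mean of the reference
#' quantities. Returned on the log10 scale.
#'
#' @param collapsed Collapsed Cq table from [collapse_replicates()].
#' @param targets Genes to report (default the six MHC isoforms).
#' @param references Reference genes (all must be present per sample).
#' @return Tibble `sample_id`, `genotype`, `gene`, `Cq`, `ref_mean_Cq`,
#'   `log10_rq`.
#' @export
relative_quantity <- function(collapsed, targets = mhc_genes(),
                              references = reference_genes()) {
  refs <- collapsed |>
    dplyr::filter(.data$gene %in% references) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_mean_Cq = mean(.data$Cq), n_refs = dplyr::n(),
                     .groups = "drop")
  if (any(refs$n_refs < length(references)) ||
      !all(unique(collapsed$sample_id) %in% refs$sample_id)) {
    abort("every sample needs all reference genes", class = "musclephys_validation_error")
  }
  collapsed |>
    dplyr::filter(.data$gene %in% targets) |>
    dplyr::left_join(refs[c("sample_id", "ref_mean_Cq")], by = "sample_id") |>
    dplyr::mutate(log10_rq = -(.data$Cq - .data$ref_mean_Cq) * log10(2)) |>
    dplyr::select("sample_id", "genotype", "gene", "Cq", "ref_mean_Cq", "log10_rq")
}

#' Within-sample isoform proportions from raw Cq
#'
#' Estimates the relative abundance of each transcript within a scope of
#' genes as `p_i = 2^-Cq_i / sum_j 2^-Cq_j` (efficiency 2). The default
#' scope is all six MHC isoforms; `scope = "nonregenerative"` excludes the
#' regenerative isoforms MHCemb (MYH3) and MHCneo (MYH8), whose high
#' expression in dystrophic muscle otherwise masks shifts among the others.
#'
#' @param collapsed Collapsed Cq table from [collapse_replicates()].
#' @param scope `"all"`, `"nonregenerative"`, or a character vector of genes.
#' @return Tibble `sample_id`, `genotype`, `gene`, `Cq`, `proportion`
#'   (proportions sum to 1 within each sample's scope).
#' @export
isoform_proportions <- function(collapsed, scope = c("all", "nonregenerative")) {
  genes <- if (identical(scope, c("all", "nonregenerative")) || identical(scope, "all")) {
    mhc_genes()
  } else if (identical(scope, "nonregenerative")) {
    mhc_nonregenerative_genes()
  } else {
    scope
  }
  dat <- dplyr::filter(collapsed, .data$gene %in% genes)
  if (!nrow(dat)) abort("empty gene scope")
  n_per <- dplyr::count(dat, .data$sample_id)
  if (any(n_per$n < 2)) abort("need at least 2 genes in scope per sample")
  dat |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = 2^(-.data$Cq) / sum(2^(-.data$Cq))) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "genotype", "gene", "Cq", "proportion")
}
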
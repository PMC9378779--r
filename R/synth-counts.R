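# Synthetic scRNA-seq count matrices with a mast-cell subpopulation and
# bimodal CPA3 expression.

#' Simulate a single-cell UMI count matrix
#'
#' Negative-binomial counts over a gene panel that includes the four
#' mast-cell markers (TPSAB1, TPSB2, MS4A2, CPA3), a small planted
#' "CPA3-high program" of genes upregulated twofold in CPA3-high mast cells,
#' and mitochondrial genes. Mast cells overexpress the markers; their CPA3
#' counts are a two-component mixture whose log-normalised modes straddle
#' the 1.5 split threshold. A small planted share of cells violates the QC
#' window (shallow cells under 1,000 detected genes, over-deep cells above
#' 75,000 UMIs, high-mitochondria cells above 20%).
#'
#' @param n_cells,n_genes matrix dimensions (the panel must exceed the QC
#'   gene minimum for the filter to be exercisable; default 2000 genes).
#' @param mast_fraction fraction of cells planted as mast cells (0 < f < 1).
#' @param cpa3_bimodal_params list with `low_mean`, `high_mean` (CPA3 NB
#'   mean counts at unit size factor) and `prop_high` (fraction of mast
#'   cells in the high mode).
#' @param seed RNG seed.
#' @param outlier_fractions list with `shallow`, `deep`, `mito` planted QC
#'   outlier fractions.
#' @param nb_size negative-binomial size (inverse overdispersion) of the
#'   counts; 4 gives the moderate overdispersion of UMI data
#'   (CV^2 = 1/mu + 1/size).
#' @return List with `counts` (a [count_matrix()]) and `truth` (tibble:
#'   cell_id, is_mast, cpa3_class, outlier, passes_qc — the QC flag is the
#'   realised predicate on the generated counts).
#' @export
simulate_counts <- function(n_cells = 3000, n_genes = 2000,
                            mast_fraction = 0.05,
                            cpa3_bimodal_params = list(low_mean = 0.8,
                                                       high_mean = 15,
                                                       prop_high = 0.4),
                            seed = 1,
                            outlier_fractions = list(shallow = 0.02,
                                                     deep = 0.01,
                                                     mito = 0.02),
                            nb_size = 4) {
  if (mast_fraction <= 0 || mast_fraction >= 1) {
    abort("mast_fraction must lie strictly between 0 and 1")
  }
  markers <- c("TPSAB1", "TPSB2", "MS4A2", "CPA3")
  program <- c("CMA1", "HDC", "SLC18A2") # planted CPA3-high program genes
  mito <- paste0("MT-", c("CO1", "CO2", "CO3", "ND1", "ND2", "ND3", "ND4",
                          "ND5", "ND6", "ATP6", "ATP8", "CYB", "RNR1"))
  n_named <- length(markers) + length(program) + length(mito)
  if (n_genes < n_named + 10) abort("n_genes too small for the fixed panel")
  genes <- c(markers, program, mito,
             sprintf("GENE%04d", seq_len(n_genes - n_named)))

  with_seed(seed, {
    is_mast <- runif(n_cells) < mast_fraction
    cpa3_class <- rep(NA_character_, n_cells)
    cpa3_class[is_mast] <- ifelse(
      runif(sum(is_mast)) < cpa3_bimodal_params$prop_high, "high", "low")

    outlier <- rep("none", n_cells)
    pool <- which(runif(n_cells) <
                    Reduce(`+`, outlier_fractions)) # candidate outliers
    if (length(pool)) {
      kinds <- sample(c("shallow", "deep", "mito"), length(pool), replace = TRUE,
                      prob = unlist(outlier_fractions))
      outlier[pool] <- kinds
    }

    # per-gene base rates, normalised to ~7000 expected UMIs per cell
    rate <- rlnorm(n_genes, 0, 1)
    names(rate) <- genes
    rate[markers] <- c(0.01, 0.01, 0.01, 0) # near-silent outside mast cells
    rate[program] <- 6
    rate[mito] <- 0 # set via mito share below
    rate <- rate / sum(rate) * 7000 * 0.92
    mito_rate <- rep(7000 * 0.08 / length(mito), length(mito))
    rate[mito] <- mito_rate

    size_factor <- rlnorm(n_cells, 0, 0.35)
    size_factor[outlier == "shallow"] <- 0.02
    size_factor[outlier == "deep"] <- 15

    mu <- matrix(rate, n_genes, n_cells) * rep(size_factor, each = n_genes)
    rownames(mu) <- genes

    # mast-marker overexpression
    if (any(is_mast)) {
      mu["TPSAB1", is_mast] <- 30 * size_factor[is_mast]
      mu["TPSB2", is_mast] <- 20 * size_factor[is_mast]
      mu["MS4A2", is_mast] <- 8 * size_factor[is_mast]
      cpa3_mu <- ifelse(cpa3_class[is_mast] == "high",
                        cpa3_bimodal_params$high_mean,
                        cpa3_bimodal_params$low_mean)
      mu["CPA3", is_mast] <- cpa3_mu * size_factor[is_mast]
      hi <- is_mast & cpa3_class == "high"
      if (any(hi, na.rm = TRUE)) {
        hi[is.na(hi)] <- FALSE
        mu[program, hi] <- mu[program, hi] * 2 # planted 2x program
      }
    }
    # high-mito cells: mitochondrial share boosted past the 20% QC ceiling
    hm <- outlier == "mito"
    if (any(hm)) mu[mito, hm] <- mu[mito, hm] * 8

    counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                     n_genes, n_cells)
    cm <- count_matrix(counts, genes,
                       sprintf("CELL%05d", seq_len(n_cells)))

    met <- qc_metrics(cm)
    truth <- tibble::tibble(
      cell_id = colnames(cm$counts),
      is_mast = is_mast, cpa3_class = cpa3_class, outlier = outlier,
      passes_qc = met$passes
    )
    list(counts = cm, truth = truth)
  })
}
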
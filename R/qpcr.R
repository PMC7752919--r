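#' Relative fold change by the delta-delta-Ct method
#'
#' Averages duplicate wells per (sample, gene, condition), forms
#' `dCt = Ct_target - Ct_reference` within each condition, then
#' `ddCt = dCt_treated - dCt_control` and the fold change `2^(-ddCt)`.
#' Perfect doubling per cycle is assumed (no efficiency correction).
#'
#' @param ct data frame of wells with columns `sample_id`, `gene`,
#'   `condition`, `ct` (and optionally `replicate`).
#' @param target target gene name.
#' @param reference endogenous reference gene name (e.g. GAPDH).
#' @param treated,control condition labels.
#' @return data frame per sample: mean Cts, `ddct` and `fold_change`.
#' @examples
#' ct <- data.frame(sample_id = "s1",
#'                  gene = rep(c("T", "GAPDH"), each = 2),
#'                  condition = rep(c("treated", "control"), 2),
#'                  ct = c(22, 24.5, 18, 18.5))
#' ddct_fold_change(ct, "T", "GAPDH", "treated", "control")
#' @export
ddct_fold_change <- function(ct, target, reference, treated, control) {
  stopifnot(all(c("sample_id", "gene", "condition", "ct") %in% names(ct)))
  samples <- unique(ct$sample_id)
  out <- do.call(rbind, lapply(samples, function(s) {
    sub <- ct[ct$sample_id == s, , drop = FALSE]
    m <- function(g, cond) {
      v <- sub$ct[sub$gene == g & sub$condition == cond]
      if (length(v) == 0)
        stop("missing Ct for sample ", s, ", gene ", g, ", condition ",
             cond, call. = FALSE)
      mean(v)
    }
    dct_t <- m(target, treated) - m(reference, treated)
    dct_c <- m(target, control) - m(reference, control)
    ddct <- dct_t - dct_c
    data.frame(sample_id = s,
               dct_treated = dct_t, dct_control = dct_c,
               ddct = ddct, fold_change = 2^(-ddct))
  }))
  rownames(out) <- NULL
  out
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Standard dilution-adjusted percent-input: the input Ct is first shifted
#' by `-log2(1 / input_fraction)` to account for the input being a diluted
#' fraction of the chromatin, then
#' `%input = 100 * 2^(adjusted_input_ct - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitated DNA (cycles, > 0).
#' @param ct_input Ct of the input DNA (cycles, > 0).
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return percent input (vectorized over the Ct arguments).
#' @examples
#' chip_percent_input(28, 25, input_fraction = 0.1)
#' @export
chip_percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  if (any(ct_ip <= 0) || any(ct_input <= 0))
    stop("Ct values must be positive", call. = FALSE)
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}
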
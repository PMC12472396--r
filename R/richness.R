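#' Motif richness of 3'-terminal extensions
#'
#' For each extension length, richness is the percentage of observed
#' unique extension sequences relative to all possible motifs of that
#' exact length: spaces of 4, 16, 64 and 256 for mono-, di-, tri- and
#' tetranucleotides. Extensions contribute only at their exact length (a
#' 5-mer extension does not contribute its 4-mer prefix).
#'
#' @param records Deviation-record data frame (see [classify_locus()]);
#'   only the `extension` column is used.
#' @param lengths Extension lengths to summarize (subset of 1:4).
#' @return Data frame with columns `length`, `space`, `observed_unique`,
#'   `richness_pct`.
#' @export
motif_richness <- function(records, lengths = 1:4) {
  stopifnot(all(lengths %in% 1:4))
  ext <- records$extension
  ext <- ext[!is.na(ext) & nzchar(ext)]
  do.call(rbind, lapply(lengths, function(l) {
    obs <- length(unique(ext[nchar(ext) == l]))
    space <- as.integer(4^l)
    data.frame(length = l, space = space, observed_unique = obs,
               richness_pct = 100 * obs / space)
  }))
}

#' Percentage of reads with non-templated 3' nucleotides
#'
#' @param records Deviation-record data frame over all collected reads at a
#'   locus.
#' @return Percentage (0-100) of records with a non-empty 3' extension.
#' @export
extension_rate <- function(records) {
  if (nrow(records) == 0L) stop("no collected reads")
  100 * mean(nzchar(records$extension) & !is.na(records$extension))
}
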
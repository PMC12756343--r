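#' Pipeline configuration
#'
#' Collects every tunable threshold of the ortholog pipeline under its
#' default value. Defaults mirror the published method: candidate homolog
#' pairs are kept within 20% of the best score for either gene
#' (`candidate_ratio = 0.8`), score margins of "at least 5%" are
#' multiplicative (`score_margin = 1.05`), the zero-synteny path requires
#' alignment coverage of more than 50% of the longer and 90% of the shorter
#' protein, microsynteny is counted over at most 10 adjacent loci per side,
#' exonic flanks extend up to 2000 bases per side, and the synteny margin of
#' rule S4 is 2.
#'
#' The remaining keys parameterize the bundled deterministic aligners:
#' BLOSUM62 with affine gaps (open 11, extend 1) and a raw-score floor for
#' proteins; match/mismatch +2/-3, seed length 11, x-drop 30 and a score
#' floor for the nucleotide seed-and-extend backend.
#'
#' @param ... named overrides of any default listed above.
#' @return A named list of class `ortholog_config`.
#' @export
ortholog_config <- function(...) {
  cfg <- list(
    candidate_ratio = 0.8,
    score_margin = 1.05,
    min_coverage_longer = 0.5,
    min_coverage_shorter = 0.9,
    synteny_window = 10L,
    synteny_delta = 2L,
    flank_len = 2000L,
    protein_matrix = "BLOSUM62",
    protein_gap_open = 11,
    protein_gap_ext = 1,
    protein_score_floor = 60,
    nt_match = 2L,
    nt_mismatch = -3L,
    nt_kmer = 11L,
    nt_xdrop = 30L,
    nt_score_floor = 50L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "ortholog_config")
}

#' Read pipeline configuration from a YAML file
#'
#' Any key of [ortholog_config()] may appear in the file; unset keys keep
#' their defaults.
#'
#' @param path YAML file of configuration overrides.
#' @return An `ortholog_config`.
#' @export
read_ortholog_config <- function(path) {
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  do.call(ortholog_config, ov)
}
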
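# Transitive-anchor orthology, anchor-keyed ortholog sets, and gene-symbol
# propagation. Ortholog pair lists are two-column data.frames
# (query_gene_id, subject_gene_id) and must be partial matchings: no gene on
# either side appears twice.

.check_one_to_one <- function(pairs, what) {
  if (anyDuplicated(pairs$query_gene_id) || anyDuplicated(pairs$subject_gene_id))
    stop(what, " is not one-to-one", call. = FALSE)
  invisible(pairs)
}

#' Transitive ortholog inference through an intermediate anchor
#'
#' Composes two one-to-one ortholog pair lists: a query gene c is
#' transitively an ortholog of primary-anchor gene a when c has an ortholog
#' b in the transitive anchor genome and b is itself an ortholog of a.
#' Query genes whose transitive-anchor ortholog has no primary-anchor
#' ortholog are not emitted — they remain anchored to the transitive anchor.
#'
#' @param query_to_anchorB data.frame (`query_gene_id`, `subject_gene_id`):
#'   orthologs between the query genome and the transitive anchor B.
#' @param anchorB_to_anchorA data.frame (`query_gene_id`, `subject_gene_id`):
#'   orthologs between anchor B (query side) and the primary anchor A.
#' @return data.frame (`query_gene_id`, `subject_gene_id`) of inferred
#'   query-to-A orthologs; one-to-one by construction.
#' @export
transitive_orthologs <- function(query_to_anchorB, anchorB_to_anchorA) {
  .check_one_to_one(query_to_anchorB, "query-to-transitive-anchor pair list")
  .check_one_to_one(anchorB_to_anchorA, "anchor-to-anchor pair list")
  m <- match(query_to_anchorB$subject_gene_id, anchorB_to_anchorA$query_gene_id)
  keep <- !is.na(m)
  out <- data.frame(
    query_gene_id = query_to_anchorB$query_gene_id[keep],
    subject_gene_id = anchorB_to_anchorA$subject_gene_id[m[keep]],
    stringsAsFactors = FALSE)
  out <- out[order(out$query_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor configuration
#'
#' Maps a clade label to its primary anchor genome and, optionally, a
#' transitive anchor through which primary-anchor orthologs are composed.
#' Anchor selection is a pure lookup on this table.
#'
#' @param clades named list; each element a list with `primary_anchor` and
#'   optionally `transitive_anchor` (genome ids).
#' @return The validated configuration, class `anchor_config`.
#' @export
anchor_config <- function(clades) {
  for (cl in names(clades)) {
    e <- clades[[cl]]
    if (is.null(e$primary_anchor))
      stop("clade '", cl, "' lacks a primary anchor", call. = FALSE)
  }
  structure(clades, class = "anchor_config")
}

#' Read an anchor configuration from YAML
#' @param path YAML file: clade label -> primary_anchor / transitive_anchor.
#' @return An [anchor_config()].
#' @export
read_anchor_config <- function(path) anchor_config(yaml::read_yaml(path))

#' Look up the anchors for a clade
#' @param config an [anchor_config()].
#' @param clade clade label.
#' @return List with `primary_anchor` and `transitive_anchor` (or `NULL`).
#' @export
select_anchor <- function(config, clade) {
  if (!clade %in% names(config))
    stop("clade '", clade, "' not in anchor configuration", call. = FALSE)
  e <- config[[clade]]
  list(primary_anchor = e$primary_anchor,
       transitive_anchor = e$transitive_anchor)
}

#' Consolidate ortholog pairs into anchor-keyed ortholog sets
#'
#' Each set is keyed by an anchor gene and lists the genes identified as its
#' orthologs across genomes, tagged `direct` or `transitive`. A member gene
#' that also has a transitive primary-anchor ortholog belongs to the primary
#' set only; members with a transitive-anchor ortholog but no primary
#' ortholog stay in the transitive anchor's sets. A member occurring in two
#' sets indicates a violated one-to-one guarantee upstream and is an error.
#'
#' @param direct_pairs data.frame of direct calls with columns
#'   `member_genome_id`, `member_gene_id`, `anchor_genome_id`,
#'   `anchor_gene_id`.
#' @param transitive_pairs optional data.frame in the same format for
#'   transitively inferred primary-anchor orthologs.
#' @return Named list of `ortholog_set` objects (name = anchor gene id),
#'   each with `anchor_gene_id`, `anchor_genome_id` and a `members`
#'   data.frame (`genome_id`, `gene_id`, `via`), deterministically ordered.
#' @export
build_ortholog_sets <- function(direct_pairs, transitive_pairs = NULL) {
  direct_pairs <- as.data.frame(direct_pairs, stringsAsFactors = FALSE)
  direct_pairs$via <- rep("direct", nrow(direct_pairs))
  members <- direct_pairs
  if (!is.null(transitive_pairs) && nrow(transitive_pairs)) {
    transitive_pairs <- as.data.frame(transitive_pairs, stringsAsFactors = FALSE)
    transitive_pairs$via <- "transitive"
    tkey <- paste(transitive_pairs$member_genome_id,
                  transitive_pairs$member_gene_id)
    # a gene promoted to the primary anchor leaves the transitive-anchor set
    drop <- paste(members$member_genome_id, members$member_gene_id) %in% tkey
    members <- rbind(members[!drop, , drop = FALSE], transitive_pairs)
  }
  if (nrow(members) == 0L) return(structure(list(), names = character()))
  key <- paste(members$member_genome_id, members$member_gene_id)
  if (anyDuplicated(key))
    stop("gene(s) assigned to two ortholog sets: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (any(members$member_gene_id == members$anchor_gene_id &
            members$member_genome_id == members$anchor_genome_id))
    stop("anchor gene listed among set members", call. = FALSE)

  members <- members[order(members$anchor_gene_id, members$member_genome_id,
                           members$member_gene_id), , drop = FALSE]
  sets <- lapply(split(members, members$anchor_gene_id), function(d) {
    structure(list(anchor_gene_id = d$anchor_gene_id[1L],
                   anchor_genome_id = d$anchor_genome_id[1L],
                   members = data.frame(genome_id = d$member_genome_id,
                                        gene_id = d$member_gene_id,
                                        via = d$via, stringsAsFactors = FALSE,
                                        row.names = NULL)),
              class = "ortholog_set")
  })
  sets[order(names(sets))]
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("ortholog_set anchored on %s (%s): %d member(s)\n",
              x$anchor_gene_id, x$anchor_genome_id, nrow(x$members)))
  invisible(x)
}

#' Propagate gene symbols from anchors to ortholog-set members
#'
#' Every member of a set receives its anchor gene's symbol, unless the
#' anchor symbol is an uninformative placeholder (by default the
#' `LOC<digits>` and `CG<digits>` classes) or the member gene is
#' blocklisted. Members that receive nothing keep their current symbol, or
#' the placeholder `LOC<gene_id>` when none is known. The operation is
#' idempotent.
#'
#' @param sets list of `ortholog_set` from [build_ortholog_sets()].
#' @param anchor_symbols named character vector: anchor gene id -> symbol.
#' @param placeholder_patterns regular expressions identifying
#'   non-propagatable symbols.
#' @param blocklist gene ids whose symbols must never be auto-updated.
#' @param member_symbols optional named character vector of current member
#'   symbols.
#' @return Named character vector: member gene id -> assigned symbol.
#' @export
propagate_gene_symbols <- function(sets, anchor_symbols,
                                   placeholder_patterns = c("^LOC\\d+$", "^CG\\d+$"),
                                   blocklist = character(),
                                   member_symbols = NULL) {
  is_placeholder <- function(sym)
    is.na(sym) | Reduce(`|`, lapply(placeholder_patterns, grepl, x = sym),
                        rep(FALSE, length(sym)))
  out <- character(0)
  for (set in sets) {
    anchor_sym <- unname(anchor_symbols[set$anchor_gene_id])
    informative <- length(anchor_sym) == 1L && !is_placeholder(anchor_sym)
    for (gid in set$members$gene_id) {
      current <- if (!is.null(member_symbols) && gid %in% names(member_symbols))
        unname(member_symbols[gid]) else paste0("LOC", gid)
      out[gid] <- if (gid %in% blocklist || !informative) current else anchor_sym
    }
  }
  out
}

#' Compare directly computed and transitively inferred ortholog pairs
#'
#' Returns the pairs present in exactly one of the two lists, tagged with
#' their provenance, for curation-style review. Both inputs must cover the
#' same query genome against the same primary anchor.
#'
#' @param direct_pairs,transitive_pairs data.frames
#'   (`query_gene_id`, `subject_gene_id`).
#' @return data.frame (`query_gene_id`, `subject_gene_id`, `only_in`); zero
#'   rows when the two lists agree exactly.
#' @export
verify_transitive_agreement <- function(direct_pairs, transitive_pairs) {
  key <- function(d) paste(d$query_gene_id, d$subject_gene_id, sep = "\r")
  kd <- key(direct_pairs); kt <- key(transitive_pairs)
  tag <- function(d, lab) {
    d <- d[, c("query_gene_id", "subject_gene_id"), drop = FALSE]
    d$only_in <- rep(lab, nrow(d))
    d
  }
  out <- rbind(tag(direct_pairs[!(kd %in% kt), , drop = FALSE], "direct"),
               tag(transitive_pairs[!(kt %in% kd), , drop = FALSE], "transitive"))
  rownames(out) <- NULL
  out
}
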
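# Deterministic genome-pair/trio simulator with planted ortholog truth.
#
# An ancestral set of protein-coding gene models (codon sequences split into
# exons, with introns and intergenic spacers) is evolved into descendant
# genomes by codon-level substitution, gene loss, tandem duplication and
# segmental inversion. Because mutations act on codons (never creating stop
# codons), protein and nucleotide divergence stay consistent. The identity
# of every descendant gene's ancestor is tracked, which yields the planted
# one-to-one ortholog truth used to validate the pipeline end to end.

#' Simulation configuration
#'
#' Defaults describe the standard validation scenario: 200 genes on 2
#' scaffolds, 5% pairwise sequence divergence, 10 gene losses, 5
#' pre-speciation duplications, 2 inversions, and no post-speciation
#' duplications. `substitution_rate` is the expected pairwise per-site
#' divergence between two descendants (each branch receives half).
#'
#' @param n_genes ancestral protein-coding genes.
#' @param n_scaffolds scaffolds the genes are distributed over.
#' @param mean_exons_per_gene mean exon count (minimum 1).
#' @param mean_exon_len mean exon length in bases (rounded to codons).
#' @param mean_intron_len,mean_intergenic_len mean spacer lengths in bases.
#' @param substitution_rate expected pairwise per-site divergence, in [0, 1).
#' @param n_duplications_pre duplications placed in the ancestor (diverged
#'   copies; resolvable through synteny, so still part of the truth).
#' @param n_duplications_post identical tandem duplications applied to one
#'   descendant after the split (ambiguous by construction; excluded from
#'   the truth).
#' @param n_losses genes deleted from one descendant.
#' @param n_inversions gene-order blocks reversed (strands flipped) in one
#'   descendant.
#' @param add_utr add an untranslated 5' exon to every gene.
#' @param seed RNG seed; identical seeds give identical output.
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_scaffolds = 2L,
                              mean_exons_per_gene = 3, mean_exon_len = 120L,
                              mean_intron_len = 60L, mean_intergenic_len = 150L,
                              substitution_rate = 0.05,
                              n_duplications_pre = 5L, n_duplications_post = 0L,
                              n_losses = 10L, n_inversions = 2L,
                              add_utr = FALSE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_scaffolds = as.integer(n_scaffolds),
              mean_exons_per_gene = mean_exons_per_gene,
              mean_exon_len = as.integer(mean_exon_len),
              mean_intron_len = as.integer(mean_intron_len),
              mean_intergenic_len = as.integer(mean_intergenic_len),
              substitution_rate = substitution_rate,
              n_duplications_pre = as.integer(n_duplications_pre),
              n_duplications_post = as.integer(n_duplications_post),
              n_losses = as.integer(n_losses),
              n_inversions = as.integer(n_inversions),
              add_utr = isTRUE(add_utr), seed = as.integer(seed))
  counts <- unlist(cfg[c("n_genes", "n_scaffolds", "n_duplications_pre",
                         "n_duplications_post", "n_losses", "n_inversions")])
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (cfg$n_genes < 1L) stop("n_genes must be at least 1", call. = FALSE)
  if (cfg$substitution_rate < 0 || cfg$substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)", call. = FALSE)
  if (cfg$n_losses > cfg$n_genes)
    stop("infeasible config: more losses than genes", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# Substitute bases at `rate` per site (uniform across the three alternatives).
.mutate_dna <- function(s, rate) {
  if (rate <= 0 || !nzchar(s)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Codon-aware substitution: per-site rate as above, but any codon turned into
# a stop is re-drawn among the non-stop alternatives at the mutated site.
.mutate_cds <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    cod0 <- (i - 1L) %/% 3L * 3L
    for (b in sample(setdiff(.BASES, ch[i]))) {
      old <- ch[i]; ch[i] <- b
      if (!paste(ch[cod0 + 1:3], collapse = "") %in% .STOPS) break
      ch[i] <- old
    }
  }
  paste(ch, collapse = "")
}

# One ancestral gene blueprint: codon sequence split over exons, plus introns.
.make_gene <- function(aid, cfg, codon_tab) {
  n_ex <- 1L + stats::rpois(1L, max(0, cfg$mean_exons_per_gene - 1))
  codons_per_exon <- pmax(8L, stats::rpois(n_ex, max(1, cfg$mean_exon_len %/% 3L)))
  n_cod <- sum(codons_per_exon)
  aa <- c("M", sample(setdiff(names(codon_tab), "*"), n_cod - 1L, replace = TRUE))
  cds <- paste(vapply(aa, function(a) {
    cc <- setdiff(codon_tab[[a]], .STOPS)
    cc[sample.int(length(cc), 1L)]
  }, ""), collapse = "")
  list(aid = aid,
       strand = sample(c("+", "-"), 1L),
       cds = cds,
       codons_per_exon = codons_per_exon,
       utr5 = if (cfg$add_utr) .random_dna(60L) else "",
       introns = if (n_ex > 1L || cfg$add_utr)
         vapply(seq_len(n_ex - 1L + as.integer(cfg$add_utr)),
                function(i) .random_dna(20L + stats::rpois(1L, cfg$mean_intron_len)),
                "") else character())
}

.mutate_gene <- function(g, rate) {
  g$cds <- .mutate_cds(g$cds, rate)
  if (nzchar(g$utr5)) g$utr5 <- .mutate_dna(g$utr5, rate)
  g$introns <- vapply(g$introns, .mutate_dna, "", rate = rate, USE.NAMES = FALSE)
  g
}

# transcript-order exon strings of a blueprint (UTR exon first when present)
.gene_exons <- function(g) {
  ends <- cumsum(g$codons_per_exon) * 3L
  starts <- c(0L, ends[-length(ends)]) + 1L
  ex <- substring(g$cds, starts, ends)
  if (nzchar(g$utr5)) ex <- c(g$utr5, ex)
  ex
}

# Materialize one descendant (list of scaffolds, each a list of blueprints
# and intergenic spacers) into an annotated_genome.
.materialize <- function(genome_id, scaffolds, cfg) {
  genes <- list(); isoforms <- list(); exons <- list(); seqs <- character()
  for (si in seq_along(scaffolds)) {
    sc_id <- sprintf("scf%02d", si)
    sc <- scaffolds[[si]]
    pos <- 0L; chunks <- character()
    for (gi in seq_along(sc$genes)) {
      g <- sc$genes[[gi]]
      spacer <- sc$intergenic[[gi]]
      chunks <- c(chunks, spacer); pos <- pos + nchar(spacer)
      ex <- .gene_exons(g)
      pre_parts <- character(2L * length(ex) - 1L)
      pre_parts[seq_along(ex) * 2L - 1L] <- ex
      if (length(g$introns)) pre_parts[seq_len(length(g$introns)) * 2L] <- g$introns
      pre <- paste(pre_parts, collapse = "")
      ends <- cumsum(nchar(pre_parts))
      ex_end <- ends[seq_along(ex) * 2L - 1L]
      ex_start <- ex_end - nchar(ex)          # 0-based within pre
      L <- nchar(pre)
      if (g$strand == "+") {
        gseq <- pre; e_start <- ex_start; e_end <- ex_end
      } else {
        gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
        e_start <- L - ex_end; e_end <- L - ex_start
      }
      gid <- paste0(genome_id, "_", g$aid)
      iid <- paste0(gid, ".t1")
      chunks <- c(chunks, gseq)
      genes[[gid]] <- data.frame(
        gene_id = gid, symbol = paste0("LOC", gid), scaffold_id = sc_id,
        span_start = NA_integer_, span_end = NA_integer_, strand = g$strand,
        stringsAsFactors = FALSE)
      isoforms[[iid]] <- data.frame(
        gene_id = gid, isoform_id = iid, protein_id = paste0(iid, ".p"),
        protein_seq = as.character(
          Biostrings::translate(Biostrings::DNAString(g$cds))),
        stringsAsFactors = FALSE)
      exons[[iid]] <- data.frame(
        isoform_id = iid, scaffold_id = sc_id,
        start = pos + e_start, end = pos + e_end, strand = g$strand,
        stringsAsFactors = FALSE)
      pos <- pos + L
    }
    chunks <- c(chunks, sc$intergenic[[length(sc$genes) + 1L]])
    seqs[sc_id] <- paste(chunks, collapse = "")
  }
  annotated_genome(genome_id,
                   do.call(rbind, genes), do.call(rbind, isoforms),
                   do.call(rbind, exons), Biostrings::DNAStringSet(seqs))
}

# Core engine shared by pair and trio simulation.
.simulate_genomes <- function(cfg, genome_ids) {
  set.seed(cfg$seed)
  codon_tab <- .codons_by_aa()
  n_desc <- length(genome_ids)

  # --- ancestor ---------------------------------------------------------
  per_scaffold <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_scaffolds + 1L)))
  aid <- 0L
  ancestor <- lapply(per_scaffold, function(ng) {
    gs <- lapply(seq_len(ng), function(i) {
      aid <<- aid + 1L
      .make_gene(sprintf("g%04d", aid), cfg, codon_tab)
    })
    list(genes = gs,
         intergenic = lapply(seq_len(ng + 1L), function(i)
           .random_dna(40L + stats::rpois(1L, cfg$mean_intergenic_len))))
  })

  # pre-speciation duplications: diverged copy inserted at a random position
  if (cfg$n_duplications_pre > 0L) {
    all_aids <- unlist(lapply(ancestor, function(s)
      vapply(s$genes, `[[`, "", "aid")))
    dup_src <- sample(all_aids, min(cfg$n_duplications_pre, length(all_aids)))
    for (src in dup_src) {
      for (si in seq_along(ancestor)) {
        hit <- which(vapply(ancestor[[si]]$genes, `[[`, "", "aid") == src)
        if (length(hit)) {
          copy <- ancestor[[si]]$genes[[hit]]
          copy$aid <- paste0(src, "d")
          copy <- .mutate_gene(copy, cfg$substitution_rate)
          ti <- sample.int(length(ancestor), 1L)
          slot <- sample.int(length(ancestor[[ti]]$genes) + 1L, 1L)
          ancestor[[ti]]$genes <- append(ancestor[[ti]]$genes, list(copy),
                                         after = slot - 1L)
          ancestor[[ti]]$intergenic <- append(
            ancestor[[ti]]$intergenic,
            list(.random_dna(40L + stats::rpois(1L, cfg$mean_intergenic_len))),
            after = slot - 1L)
          break
        }
      }
    }
  }

  # --- descendants ------------------------------------------------------
  branch_rate <- cfg$substitution_rate / 2
  descendants <- lapply(seq_len(n_desc), function(d) {
    lapply(ancestor, function(sc) {
      sc$genes <- lapply(sc$genes, .mutate_gene, rate = branch_rate)
      sc$intergenic <- lapply(sc$intergenic, .mutate_dna, rate = branch_rate)
      sc
    })
  })
  names(descendants) <- genome_ids

  desc_aids <- function(d) unlist(lapply(descendants[[d]], function(s)
    vapply(s$genes, `[[`, "", "aid")))
  locate <- function(d, aid) {
    for (si in seq_along(descendants[[d]])) {
      hit <- which(vapply(descendants[[d]][[si]]$genes, `[[`, "", "aid") == aid)
      if (length(hit)) return(c(si, hit))
    }
    NULL
  }

  event_pool <- desc_aids(1L)
  ambiguous_aids <- character()
  lost_aids <- character()

  # post-speciation duplications: identical tandem copy in one descendant
  if (cfg$n_duplications_post > 0L) {
    srcs <- sample(event_pool, min(cfg$n_duplications_post, length(event_pool)))
    event_pool <- setdiff(event_pool, srcs)
    for (src in srcs) {
      d <- sample.int(n_desc, 1L)
      at <- locate(d, src)
      copy <- descendants[[d]][[at[1L]]]$genes[[at[2L]]]
      copy$aid <- paste0(src, "x")
      descendants[[d]][[at[1L]]]$genes <- append(
        descendants[[d]][[at[1L]]]$genes, list(copy), after = at[2L])
      descendants[[d]][[at[1L]]]$intergenic <- append(
        descendants[[d]][[at[1L]]]$intergenic,
        list(.random_dna(40L + stats::rpois(1L, cfg$mean_intergenic_len))),
        after = at[2L])
      ambiguous_aids <- c(ambiguous_aids, src, copy$aid)
    }
  }

  # losses: delete the gene from one descendant
  if (cfg$n_losses > 0L) {
    srcs <- sample(event_pool, min(cfg$n_losses, length(event_pool)))
    event_pool <- setdiff(event_pool, srcs)
    for (src in srcs) {
      d <- sample.int(n_desc, 1L)
      at <- locate(d, src)
      descendants[[d]][[at[1L]]]$genes[[at[2L]]] <- NULL
      descendants[[d]][[at[1L]]]$intergenic <-
        descendants[[d]][[at[1L]]]$intergenic[-at[2L]]
      lost_aids <- c(lost_aids, src)
    }
  }

  # inversions: reverse a block of gene order, flipping strands
  if (cfg$n_inversions > 0L) {
    for (i in seq_len(cfg$n_inversions)) {
      d <- sample.int(n_desc, 1L)
      si <- sample.int(length(descendants[[d]]), 1L)
      ng <- length(descendants[[d]][[si]]$genes)
      if (ng < 2L) next
      len <- sample(2:min(5L, ng), 1L)
      from <- sample.int(ng - len + 1L, 1L)
      idx <- from:(from + len - 1L)
      block <- rev(descendants[[d]][[si]]$genes[idx])
      block <- lapply(block, function(g) {
        g$strand <- if (g$strand == "+") "-" else "+"
        g
      })
      descendants[[d]][[si]]$genes[idx] <- block
    }
  }

  genomes <- lapply(genome_ids, function(gid)
    .materialize(gid, descendants[[gid]], cfg))
  names(genomes) <- genome_ids

  # planted truth per genome pair
  truth_for <- function(a, b) {
    ga <- genomes[[a]]$genes$gene_id
    gb <- genomes[[b]]$genes$gene_id
    aids_a <- sub(paste0("^", a, "_"), "", ga)
    aids_b <- sub(paste0("^", b, "_"), "", gb)
    base_amb <- unique(sub("x$", "", ambiguous_aids))
    shared <- setdiff(intersect(aids_a, aids_b), c(ambiguous_aids, base_amb))
    amb <- c(ga[aids_a %in% c(ambiguous_aids, base_amb)],
             gb[aids_b %in% c(ambiguous_aids, base_amb)])
    lost_a <- ga[aids_a %in% setdiff(lost_aids, aids_b)]
    lost_b <- gb[aids_b %in% setdiff(lost_aids, aids_a)]
    structure(list(
      true_ortholog_pairs = data.frame(
        query_gene_id = paste0(a, "_", sort(shared)),
        subject_gene_id = paste0(b, "_", sort(shared)),
        stringsAsFactors = FALSE),
      ambiguous_genes = sort(unique(amb)),
      lost_genes = sort(unique(c(lost_a, lost_b)))), class = "planted_truth")
  }

  list(genomes = genomes, truth_for = truth_for)
}

#' Simulate an annotated genome pair with planted ortholog truth
#'
#' @param config a [simulation_config()].
#' @param genome_ids identifiers of the two descendant genomes.
#' @return List with elements `query` and `subject` ([annotated_genome()]
#'   objects) and `truth`, a `planted_truth` list holding
#'   `true_ortholog_pairs` (data.frame of one-to-one ortholog gene pairs),
#'   `ambiguous_genes` (members of identical post-speciation duplicate
#'   clusters, never part of the truth) and `lost_genes` (genes whose
#'   counterpart was deleted).
#' @export
simulate_genome_pair <- function(config = simulation_config(),
                                 genome_ids = c("A", "B")) {
  stopifnot(length(genome_ids) == 2L)
  sim <- .simulate_genomes(config, genome_ids)
  list(query = sim$genomes[[1L]], subject = sim$genomes[[2L]],
       truth = sim$truth_for(genome_ids[1L], genome_ids[2L]))
}

#' Simulate a three-genome set for transitive-orthology validation
#'
#' Three descendants of one ancestor; events (losses, duplications,
#' inversions) are distributed among them. Pairwise divergence is
#' approximately `substitution_rate` for every pair.
#'
#' @inheritParams simulate_genome_pair
#' @param genome_ids identifiers of the three genomes (query, transitive
#'   anchor, primary anchor).
#' @return List with `genomes` (named list of three [annotated_genome()])
#'   and `truth` (function of two genome ids returning the pair's
#'   `planted_truth`).
#' @export
simulate_genome_trio <- function(config = simulation_config(),
                                 genome_ids = c("C", "B", "A")) {
  stopifnot(length(genome_ids) == 3L)
  sim <- .simulate_genomes(config, genome_ids)
  list(genomes = sim$genomes, truth = sim$truth_for)
}

#' Permute gene order while keeping every sequence
#'
#' Rebuilds a genome with the gene loci of each scaffold in a random order,
#' preserving each locus' sequence, exon structure, strand and the original
#' intergenic spacers. Protein and spliced exonic sequences are unchanged;
#' only the neighborhood structure (and hence microsynteny) is destroyed.
#'
#' @param genome an [annotated_genome()].
#' @param seed RNG seed for the permutation.
#' @return A new `annotated_genome` with permuted gene order.
#' @export
shuffle_gene_order <- function(genome, seed = 1L) {
  set.seed(seed)
  genes <- genome$genes; exons <- genome$exons
  new_seq <- character(); new_genes <- list(); new_exons <- list()
  for (sc in names(genome$seq)) {
    g <- genes[genes$scaffold_id == sc, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    full <- genome$seq[[sc]]
    n <- nrow(g)
    if (n == 0L) { new_seq[sc] <- as.character(full); next }
    bounds <- c(0L, g$span_end)                 # gap i precedes gene i
    gaps <- vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(full, bounds[i] + 1L,
                                      g$span_start[i])), "")
    tail_gap <- as.character(Biostrings::subseq(full, g$span_end[n] + 1L,
                                                length(full)))
    spans <- vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(full, g$span_start[i] + 1L,
                                      g$span_end[i])), "")
    perm <- sample.int(n)
    pos <- 0L; chunks <- character()
    for (k in seq_len(n)) {
      i <- perm[k]
      chunks <- c(chunks, gaps[k]); pos <- pos + nchar(gaps[k])
      shift <- pos - g$span_start[i]
      gi <- g[i, ]; gi$span_start <- gi$span_start + shift
      gi$span_end <- gi$span_end + shift
      new_genes[[gi$gene_id]] <- gi
      iso <- genome$isoforms$isoform_id[genome$isoforms$gene_id == gi$gene_id]
      e <- exons[exons$isoform_id %in% iso, , drop = FALSE]
      e$start <- e$start + shift; e$end <- e$end + shift
      new_exons[[gi$gene_id]] <- e
      chunks <- c(chunks, spans[i]); pos <- pos + nchar(spans[i])
    }
    chunks <- c(chunks, tail_gap)
    new_seq[sc] <- paste(chunks, collapse = "")
  }
  ng <- do.call(rbind, new_genes)
  ng$rank <- NULL
  annotated_genome(genome$genome_id, ng, genome$isoforms,
                   do.call(rbind, new_exons), Biostrings::DNAStringSet(new_seq))
}
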
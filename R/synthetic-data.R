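# Synthetic multipartite genomes with known truth. Every statistical
# structure the pipeline measures is controllable: per-replicon length and
# target G+C, codon-usage weights, COG-category mixtures, terminal inverted
# repeats with a target per-base divergence (implanted as an exact mutation
# count, so realized divergence equals the target up to rounding), implanted
# motifs, replication-marker cassettes, and a tiered pangenome
# presence/absence matrix over a configurable synthetic taxonomy with a hit
# table consistent with it. All randomness flows from one seed; the
# caller's RNG state is left untouched.

#' Codon weights at a target G+C with a fixed rank-spreading tilt
#'
#' Base weights follow the per-position G+C probability (so coding G+C tracks
#' the target); a fixed deterministic multiplicative tilt then spreads
#' within-G+C-class codons apart, emulating the distinct codon preferences of
#' real genomes (without it, codons of equal G+C would be exactly
#' equiprobable and their observed ranks pure noise).
#'
#' @param gc Target G+C fraction.
#' @param spread Log-scale half-range of the tilt (default 0.5; 0 disables).
#' @return Named normalized 64-vector over the codons.
#' @export
gc_codon_weights <- function(gc, spread = 0.5) {
  codons <- all_codons()
  gcc <- vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("G", "C")),
                numeric(1))
  w <- (gc / 2)^gcc * ((1 - gc) / 2)^(3 - gcc)
  i <- seq_along(codons)
  tilt <- 2 * (((i * 37) %% 64) / 63) - 1   # fixed pseudo-random in [-1, 1]
  w <- w * exp(spread * tilt)
  stats::setNames(w / sum(w), codons)
}

#' Invert the rank order of a weight vector
#'
#' The codon with the largest weight receives the smallest, and so on; used
#' to construct maximally rank-discordant codon usage.
#'
#' @param w Named weight vector.
#' @return Named vector with the same values assigned in reversed rank order.
#' @export
inverted_rank_weights <- function(w) {
  out <- w
  out[order(w, decreasing = TRUE)] <- sort(w)
  out / sum(out)
}

#' Specification of one synthetic replicon
#'
#' @param id Replicon id.
#' @param length Length in bp.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param target_gc Intergenic G+C fraction.
#' @param codon_weights Normalized 64-vector; coding sequence is drawn
#'   codon-by-codon from it (start codon forced to ATG, one stop at the end).
#' @param n_cds Number of CDS.
#' @param cds_length_mean,cds_length_sd CDS length distribution in codons
#'   (normal, floored at 50).
#' @param cog_mixture Named probability vector over COG category letters.
#' @param tir \code{NULL} or \code{list(length=, mutation_rate=, share=,
#'   share_divergence=)}: the left terminus is copied (for the first member
#'   of a \code{share} group, verbatim; for later members, mutated at
#'   \code{share_divergence}) and its copy, mutated at \code{mutation_rate},
#'   is reverse-complemented onto the right terminus. Rates are realized as
#'   exact counts \code{round(rate * length)}.
#' @param motifs \code{NULL} or list of \code{list(motif=, positions=)};
#'   each motif is implanted at the nearest intergenic position to each
#'   requested position (implanting never overwrites a CDS), and the realized
#'   positions are recorded in the truth tables.
#' @param marker_cassette \code{NULL}, \code{"chromosomal"},
#'   \code{"plasmid"} or \code{"incomplete-chromosomal"}: names a block of
#'   consecutive CDS near the replicon middle after the corresponding
#'   replication markers.
#' @param tier_mixture Named probabilities over gene tiers
#'   \code{strain-unique}, \code{genus-core}, \code{family-core},
#'   \code{universal}.
#' @param n_core_unique Number of genes listed in the core-gene table as
#'   unique to this replicon.
#' @param truth_label The class label the generator intends.
#' @return A \code{replicon_spec} list.
#' @export
replicon_spec <- function(id, length, topology = "linear", target_gc = 0.6,
                          codon_weights = gc_codon_weights(target_gc),
                          n_cds = 50L, cds_length_mean = 280, cds_length_sd = 60,
                          cog_mixture = c(S = 1), tir = NULL, motifs = NULL,
                          marker_cassette = NULL,
                          tier_mixture = c("strain-unique" = 1),
                          n_core_unique = 0L, truth_label = NA_character_) {
  stopifnot(abs(sum(codon_weights) - 1) < 1e-6, length(codon_weights) == 64L)
  cog_mixture <- cog_mixture / sum(cog_mixture)
  tier_mixture <- tier_mixture / sum(tier_mixture)
  if (!is.null(tir)) {
    stopifnot(tir$length < length / 2)
    if (is.null(tir$share)) tir$share <- NA_character_
    if (is.null(tir$share_divergence)) tir$share_divergence <- 0
  }
  structure(list(id = id, length = as.integer(length), topology = topology,
                 target_gc = target_gc, codon_weights = codon_weights,
                 n_cds = as.integer(n_cds), cds_length_mean = cds_length_mean,
                 cds_length_sd = cds_length_sd, cog_mixture = cog_mixture,
                 tir = tir, motifs = motifs, marker_cassette = marker_cassette,
                 tier_mixture = tier_mixture,
                 n_core_unique = as.integer(n_core_unique),
                 truth_label = truth_label),
            class = "replicon_spec")
}

#' Default synthetic taxonomy
#'
#' One focal strain, 3 further genomes of the focal genus, 6 further genomes
#' of the focal family, 10 outgroup genomes.
#'
#' @return Data frame: genome_id, strain, genus, family.
#' @export
default_taxonomy <- function() {
  data.frame(
    genome_id = c("FOCAL", paste0("GEN", 1:3), paste0("FAM", 1:6),
                  paste0("OUT", 1:10)),
    strain = c("FOCAL", paste0("GEN", 1:3), paste0("FAM", 1:6),
               paste0("OUT", 1:10)),
    genus = c(rep("FocalGenus", 4L), paste0("FamGenus", 1:6),
              paste0("OutGenus", 1:10)),
    family = c(rep("FocalFamily", 10L), paste0("OutFamily", 1:10)),
    stringsAsFactors = FALSE)
}

#' Per-tier presence probabilities outside the focal genome
#'
#' @return Named list: for each tier, probabilities for genomes of the focal
#'   genus, the focal family (other genera) and the outgroup.
#' @export
default_tier_presence <- function() {
  list("strain-unique" = c(genus = 0,    family = 0,    outgroup = 0),
       "genus-core"    = c(genus = 0.95, family = 0.05, outgroup = 0.05),
       "family-core"   = c(genus = 0.95, family = 0.95, outgroup = 0.05),
       "universal"     = c(genus = 0.95, family = 0.95, outgroup = 0.95))
}

mutate_exact <- function(sequence, n_mut) {
  if (n_mut <= 0L) return(sequence)
  ch <- seq_chars(sequence)
  pos <- sample.int(length(ch), n_mut)
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

draw_cds_sequence <- function(n_codons, weights) {
  codons <- names(weights)
  stops <- stop_codons()
  body_w <- weights[setdiff(codons, stops)]
  stop_w <- weights[stops]
  if (sum(stop_w) <= 0) stop_w <- stats::setNames(rep(1, 3), stops)
  body <- sample(names(body_w), n_codons - 2L, replace = TRUE,
                 prob = body_w / sum(body_w))
  stopc <- sample(stops, 1L, prob = stop_w / sum(stop_w))
  paste(c("ATG", body, stopc), collapse = "")
}

marker_products <- function(cassette) {
  switch(cassette,
    chromosomal = c("chromosomal replication initiation protein dnaA",
                    "DNA polymerase III beta sliding clamp dnaN",
                    "chromosome partitioning protein parA",
                    "chromosome partitioning protein parB",
                    "DNA gyrase subunit A gyrA",
                    "DNA gyrase subunit B gyrB"),
    plasmid = c("plasmid replication iteron protein rep1",
                "plasmid replicative DNA helicase rep2",
                "partitioning protein parA",
                "partitioning protein parB"),
    `incomplete-chromosomal` = c("DNA polymerase III beta sliding clamp dnaN",
                                 "partitioning protein parA"),
    stop("unknown marker cassette: ", cassette, call. = FALSE))
}

#' Generate a synthetic multipartite genome with truth tables
#'
#' @param specs List of \code{\link{replicon_spec}}s.
#' @param seed Integer seed fixing all randomness.
#' @param taxonomy See \code{\link{default_taxonomy}}.
#' @param tier_presence See \code{\link{default_tier_presence}}.
#' @param genome_id Genome id (the focal genome is the taxonomy's first row).
#' @param out_dir Optional directory; when given, GenBank, FASTA, annotation
#'   TSV, 13-column hit TSV, subject-mapping TSV, grouping TSV, core-gene TSV
#'   and truth-label TSV files are written into it.
#' @return List with \code{genome}, \code{annotations}, \code{hits} (schema
#'   of \code{\link{read_hit_table}}), \code{subject_to_genome},
#'   \code{grouping}, \code{core_genes}, \code{query_replicon} and
#'   \code{truth} (realized G+C, codon counts, COG counts, TIR info, motif
#'   positions, gene tiers, presence matrix, labels).
#' @export
generate_genome <- function(specs, seed, taxonomy = default_taxonomy(),
                            tier_presence = default_tier_presence(),
                            genome_id = "synthetic", out_dir = NULL) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "replicon_spec")))
  with_seed(seed, {
    # feasibility before any output
    for (sp in specs) {
      tirlen <- if (is.null(sp$tir)) 0L else sp$tir$length
      min_coding <- sp$n_cds * 3L * 50L
      if (2L * tirlen + min_coding + 20L * (sp$n_cds + 1L) > sp$length)
        stop("infeasible spec for ", sp$id,
             ": CDS + TIR do not fit in ", sp$length, " bp", call. = FALSE)
    }
    share_blocks <- list()
    reps <- list()
    truth <- list(gc = c(), codon_counts = list(), cog_counts = list(),
                  tir = list(), motifs = list(), markers = list(),
                  gene_tier = NULL, presence = NULL, labels = c())
    annotations <- NULL
    gene_rows <- NULL

    for (sp in specs) {
      built <- build_replicon(sp, share_blocks)
      share_blocks <- built$share_blocks
      reps[[sp$id]] <- built$replicon
      truth$gc[sp$id] <- built$gc
      truth$tir[[sp$id]] <- built$tir_truth
      truth$motifs[[sp$id]] <- built$motif_truth
      truth$markers[[sp$id]] <- built$marker_truth
      truth$codon_counts[[sp$id]] <- built$codon_truth
      ann <- built$annotations
      annotations <- rbind(annotations, ann$table)
      truth$cog_counts[[sp$id]] <- ann$letter_counts
      gene_rows <- rbind(gene_rows,
                         data.frame(gene_id = built$replicon$cds$locus_tag,
                                    replicon_id = sp$id,
                                    tier = built$tiers,
                                    stringsAsFactors = FALSE))
      truth$labels[sp$id] <- sp$truth_label
    }

    g <- genome(genome_id, reps, strain = taxonomy$strain[1L],
                genus = taxonomy$genus[1L], family = taxonomy$family[1L])

    # tiered pangenome presence matrix + consistent hit table
    pan <- build_pangenome(gene_rows, taxonomy, tier_presence)
    truth$gene_tier <- gene_rows
    truth$presence <- pan$presence

    # core-gene table: prefer conserved genes as "core"
    core <- NULL
    for (sp in specs) {
      if (sp$n_core_unique <= 0L) next
      cand <- gene_rows[gene_rows$replicon_id == sp$id &
                        gene_rows$tier %in% c("genus-core", "family-core",
                                              "universal"), "gene_id"]
      if (length(cand) < sp$n_core_unique)
        cand <- gene_rows$gene_id[gene_rows$replicon_id == sp$id]
      core <- rbind(core, data.frame(
        gene_id = cand[seq_len(min(sp$n_core_unique, length(cand)))],
        replicon_id = sp$id, stringsAsFactors = FALSE))
    }
    if (is.null(core)) core <- data.frame(gene_id = character(),
                                          replicon_id = character())

    out <- list(genome = g, annotations = annotations, hits = pan$hits,
                subject_to_genome = pan$subject_to_genome,
                grouping = taxonomy[, c("genome_id", "strain", "genus", "family")],
                core_genes = core,
                query_replicon = stats::setNames(gene_rows$replicon_id,
                                                 gene_rows$gene_id),
                truth = truth)
    audit_generated(out)
    if (!is.null(out_dir)) write_synthetic(out, out_dir)
    out
  })
}

build_replicon <- function(sp, share_blocks) {
  tirlen <- if (is.null(sp$tir)) 0L else sp$tir$length
  lens <- pmax(50L, round(stats::rnorm(sp$n_cds, sp$cds_length_mean,
                                       sp$cds_length_sd)))
  total_coding <- sum(lens) * 3L
  avail <- sp$length - 2L * tirlen
  spare <- avail - total_coding - 20L * (sp$n_cds + 1L)
  if (spare < 0L)
    stop("infeasible spec for ", sp$id, ": drawn CDS lengths exceed replicon",
         call. = FALSE)
  props <- diff(c(0, sort(stats::runif(sp$n_cds)), 1))
  gaps <- 20L + floor(spare * props)
  gaps[sp$n_cds + 1L] <- avail - total_coding - sum(gaps[seq_len(sp$n_cds)])

  strands <- sample(c("+", "-"), sp$n_cds, replace = TRUE)
  cds_seqs <- vapply(lens, draw_cds_sequence, character(1),
                     weights = sp$codon_weights)
  segments <- character(2L * sp$n_cds + 1L)
  starts <- integer(sp$n_cds); ends <- integer(sp$n_cds)
  pos <- tirlen
  for (i in seq_len(sp$n_cds)) {
    segments[2L * i - 1L] <- random_dna(gaps[i], sp$target_gc)
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    ends[i] <- pos + lens[i] * 3L
    segments[2L * i] <- if (strands[i] == "+") cds_seqs[i] else revcomp(cds_seqs[i])
    pos <- ends[i]
  }
  segments[2L * sp$n_cds + 1L] <- random_dna(gaps[sp$n_cds + 1L], sp$target_gc)
  core_seq <- paste(segments, collapse = "")

  tir_truth <- NULL
  if (tirlen > 0L) {
    tir <- sp$tir
    if (!is.na(tir$share) && !is.null(share_blocks[[tir$share]])) {
      master <- share_blocks[[tir$share]]
      left <- mutate_exact(master, round(tir$share_divergence * tirlen))
    } else {
      left <- random_dna(tirlen, sp$target_gc)
      if (!is.na(tir$share)) share_blocks[[tir$share]] <- left
    }
    n_mut <- round(tir$mutation_rate * tirlen)
    right_src <- mutate_exact(left, n_mut)
    sequence <- paste0(left, core_seq, revcomp(right_src))
    tir_truth <- list(length = tirlen, n_mutations = n_mut,
                      identity = 100 * (1 - n_mut / tirlen))
  } else {
    sequence <- core_seq
  }
  stopifnot(nchar(sequence) == sp$length)

  # motifs: nearest intergenic placement, never overwriting a CDS or TIR
  motif_truth <- NULL
  if (!is.null(sp$motifs)) {
    occupied <- cbind(starts, ends)
    for (m in sp$motifs) {
      mlen <- nchar(m$motif)
      for (p in m$positions) {
        at <- nearest_intergenic(p, mlen, sp$length, occupied, tirlen)
        if (is.na(at)) next
        substr(sequence, at, at + mlen - 1L) <- m$motif
        motif_truth <- rbind(motif_truth,
                             data.frame(motif = m$motif, position = at))
      }
    }
  }

  # marker cassette: rename a block of consecutive mid-replicon CDS
  products <- rep("hypothetical protein", sp$n_cds)
  marker_truth <- NULL
  if (!is.null(sp$marker_cassette)) {
    prods <- marker_products(sp$marker_cassette)
    i0 <- max(1L, floor(sp$n_cds / 2) - length(prods) + 1L)
    idx <- seq(i0, length.out = length(prods))
    stopifnot(max(idx) <= sp$n_cds)
    products[idx] <- prods
    marker_truth <- data.frame(rank = idx, product = prods)
  }

  tags <- sprintf("%s_%05d", sp$id, seq_len(sp$n_cds) * 5L)
  cds <- data.frame(locus_tag = tags, start = starts, end = ends,
                    strand = strands, partial = FALSE, product = products,
                    translation = NA_character_, stringsAsFactors = FALSE)
  cds$translation <- vapply(cds_seqs, function(s) {
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    sub("\\*$", "", p)
  }, character(1), USE.NAMES = FALSE)
  rep_obj <- replicon(sp$id, sequence, sp$topology, cds)

  # COG letters per gene
  letters_pool <- names(sp$cog_mixture)
  lets <- sample(letters_pool, sp$n_cds, replace = TRUE, prob = sp$cog_mixture)
  second <- stats::runif(sp$n_cds) < 0.10
  lets2 <- sample(letters_pool, sp$n_cds, replace = TRUE, prob = sp$cog_mixture)
  lab <- ifelse(second & lets2 != lets, paste0(lets, lets2), lets)
  unannot <- stats::runif(sp$n_cds) < 0.05
  lab[unannot] <- ""
  ann_table <- data.frame(gene_id = tags, cog_letters = lab,
                          description = NA_character_, stringsAsFactors = FALSE)
  letter_counts <- table(factor(unlist(strsplit(lab[!unannot], "")),
                                levels = sort(unique(unlist(strsplit(paste(lab, collapse = ""), ""))))))

  # codon truth from the drawn coding sequences
  tri <- unlist(lapply(cds_seqs, function(s)
    substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))))
  codon_truth <- table(factor(tri, levels = all_codons()))

  tiers <- sample(names(sp$tier_mixture), sp$n_cds, replace = TRUE,
                  prob = sp$tier_mixture)

  list(replicon = rep_obj, share_blocks = share_blocks,
       gc = gc_content(sequence), tir_truth = tir_truth,
       motif_truth = motif_truth, marker_truth = marker_truth,
       annotations = list(table = ann_table, letter_counts = letter_counts),
       codon_truth = codon_truth, tiers = tiers)
}

nearest_intergenic <- function(p, mlen, len, occupied, tirlen) {
  lo <- tirlen + 1L
  hi <- len - tirlen - mlen
  cand <- seq(max(lo, p - 5000L), min(hi, p + 5000L))
  if (!length(cand)) return(NA_integer_)
  free <- !vapply(cand, function(x) {
    any(x <= occupied[, 2L] & (x + mlen - 1L) >= occupied[, 1L])
  }, logical(1))
  if (!any(free)) return(NA_integer_)
  cand <- cand[free]
  cand[which.min(abs(cand - p))]
}

build_pangenome <- function(gene_rows, taxonomy, tier_presence) {
  genomes <- taxonomy$genome_id
  focal <- genomes[1L]
  klass <- ifelse(taxonomy$genome_id == focal, "focal",
           ifelse(taxonomy$genus == taxonomy$genus[1L], "genus",
           ifelse(taxonomy$family == taxonomy$family[1L], "family", "outgroup")))
  n_genes <- nrow(gene_rows)
  presence <- matrix(FALSE, n_genes, length(genomes),
                     dimnames = list(gene_rows$gene_id, genomes))
  presence[, focal] <- TRUE
  for (j in seq_along(genomes)) {
    if (klass[j] == "focal") next
    p <- vapply(gene_rows$tier, function(t) tier_presence[[t]][[klass[j]]],
                numeric(1))
    presence[, j] <- stats::runif(n_genes) < p
  }
  # hit table consistent with the presence truth
  rows <- list()
  qlen <- stats::setNames(rep(200L, n_genes), gene_rows$gene_id)
  for (j in seq_along(genomes)) {
    if (klass[j] == "focal") next
    pres <- which(presence[, j])
    if (length(pres)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = gene_rows$gene_id[pres],
        subject_id = sprintf("%s_p%05d", genomes[j], pres),
        percent_identity = 80, alignment_length = 200,
        evalue = 1e-50, bitscore = 300, query_length = 200,
        genome_id = genomes[j], stringsAsFactors = FALSE)
    }
    abs_ <- which(!presence[, j])
    weak <- abs_[stats::runif(length(abs_)) < 0.10]
    if (length(weak)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = gene_rows$gene_id[weak],
        subject_id = sprintf("%s_w%05d", genomes[j], weak),
        percent_identity = 20, alignment_length = 180,
        evalue = 1e-5, bitscore = 60, query_length = 200,
        genome_id = genomes[j], stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  subject_to_genome <- stats::setNames(hits$genome_id, hits$subject_id)
  list(presence = presence, hits = hits, subject_to_genome = subject_to_genome)
}

# generation-time self-consistency audit
audit_generated <- function(out) {
  for (id in names(out$genome$replicons)) {
    r <- out$genome$replicons[[id]]
    seqs <- cds_sequences(r)
    if (length(seqs) && !all(startsWith(seqs, "ATG")))
      stop("internal audit failed: CDS extraction mismatch on ", id,
           call. = FALSE)
    tt <- out$truth$tir[[id]]
    if (!is.null(tt)) {
      left <- substr(r$sequence, 1L, tt$length)
      right <- revcomp(substr(r$sequence, r$length - tt$length + 1L, r$length))
      d <- sum(seq_chars(left) != seq_chars(right))
      if (d != tt$n_mutations)
        stop("internal audit failed: TIR divergence mismatch on ", id,
             call. = FALSE)
    }
    mt <- out$truth$motifs[[id]]
    if (!is.null(mt)) {
      for (k in seq_len(nrow(mt))) {
        if (substr(r$sequence, mt$position[k],
                   mt$position[k] + nchar(mt$motif[k]) - 1L) != mt$motif[k])
          stop("internal audit failed: motif not at recorded position on ", id,
               call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

write_synthetic <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genbank(out$genome, file.path(out_dir, "genome.gbk"))
  write_fasta(vapply(out$genome$replicons, `[[`, character(1), "sequence"),
              file.path(out_dir, "genome.fasta"))
  write_tsv(out$annotations, file.path(out_dir, "annotations.tsv"))
  h <- out$hits
  hit12 <- data.frame(h$query_id, h$subject_id, h$percent_identity,
                      h$alignment_length, 0L, 0L, 1L, h$alignment_length,
                      1L, h$alignment_length, h$evalue, h$bitscore,
                      h$query_length)
  utils::write.table(hit12, file.path(out_dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(data.frame(subject_id = names(out$subject_to_genome),
                       genome_id = unname(out$subject_to_genome)),
            file.path(out_dir, "subject_map.tsv"))
  write_tsv(out$grouping, file.path(out_dir, "grouping.tsv"))
  write_tsv(out$core_genes, file.path(out_dir, "core_genes.tsv"))
  write_tsv(data.frame(replicon_id = names(out$truth$labels),
                       truth_label = unname(out$truth$labels)),
            file.path(out_dir, "truth_labels.tsv"))
  invisible(out_dir)
}

#' The Embleya-like preset
#'
#' Four replicons emulating the measured shape of a Streptomycetaceae
#' multipartite genome at roughly one tenth linear scale: a 700 kb linear
#' chromosome and a 420 kb chromosome-like linear secondary replicon (both
#' G+C 0.716, shared 2.1 kb TIR diverged by 5e-4 per base), plus a 30 kb
#' linear and a 21 kb circular plasmid at G+C 0.691/0.695 with plasmid-like
#' codon usage, COG mixtures and strain-specific gene tiers.
#'
#' @param scale Linear scale factor applied to lengths, TIR length and CDS
#'   counts (default 1).
#' @return List of \code{\link{replicon_spec}}s.
#' @export
preset_embleya <- function(scale = 1) {
  chr_mix <- c(E = 0.11, G = 0.09, K = 0.12, T = 0.08, P = 0.07, I = 0.05,
               Q = 0.06, C = 0.06, J = 0.05, L = 0.04, M = 0.05, O = 0.04,
               F = 0.03, H = 0.04, D = 0.02, N = 0.01, U = 0.02, V = 0.02,
               S = 0.04)
  pls_mix <- c(L = 0.18, U = 0.12, V = 0.10, S = 0.25, K = 0.06, D = 0.05,
               T = 0.04, O = 0.05, M = 0.05, C = 0.03, J = 0.02, E = 0.01,
               G = 0.01, P = 0.01, H = 0.02)
  chr_tier <- c("universal" = 0.35, "family-core" = 0.30,
                "genus-core" = 0.30, "strain-unique" = 0.05)
  sec_tier <- c("genus-core" = 0.70, "strain-unique" = 0.15,
                "family-core" = 0.10, "universal" = 0.05)
  pls_tier <- c("strain-unique" = 0.85, "genus-core" = 0.10,
                "family-core" = 0.03, "universal" = 0.02)
  w_chr <- gc_codon_weights(0.716)
  n <- function(x) max(4L, round(x * scale))
  tirlen <- max(300L, round(2100 * scale))
  parS <- "GTTTCACGTGAAAC"
  list(
    replicon_spec("CHR", round(700000 * scale), "linear", 0.716, w_chr,
                  n_cds = n(220), cog_mixture = chr_mix,
                  tir = list(length = tirlen, mutation_rate = 5e-4,
                             share = "tirA", share_divergence = 5e-4),
                  motifs = list(list(motif = parS,
                                     positions = round(c(0.3, 0.45, 0.6) *
                                                         700000 * scale))),
                  marker_cassette = "chromosomal", tier_mixture = chr_tier,
                  n_core_unique = 20L, truth_label = "chromosome"),
    replicon_spec("EEC1", round(420000 * scale), "linear", 0.716, w_chr,
                  n_cds = n(200), cog_mixture = chr_mix,
                  tir = list(length = tirlen, mutation_rate = 5e-4,
                             share = "tirA", share_divergence = 5e-4),
                  marker_cassette = "incomplete-chromosomal",
                  tier_mixture = sec_tier, n_core_unique = 10L,
                  truth_label = "secondary chromosome"),
    replicon_spec("EEC2", round(30000 * scale), "linear", 0.691,
                  gc_codon_weights(0.691), n_cds = n(18),
                  cds_length_mean = 100, cds_length_sd = 15,
                  cog_mixture = pls_mix, tier_mixture = pls_tier,
                  truth_label = "plasmid"),
    replicon_spec("EEC3", round(21000 * scale), "circular", 0.695,
                  gc_codon_weights(0.695), n_cds = n(12),
                  cds_length_mean = 100, cds_length_sd = 15,
                  cog_mixture = pls_mix,
                  motifs = list(list(motif = parS,
                                     positions = round(c(0.3, 0.7) *
                                                         21000 * scale))),
                  marker_cassette = "plasmid", tier_mixture = pls_tier,
                  truth_label = "plasmid"))
}

#' Preset covering all five replicon classes
#'
#' The Embleya-like preset plus a chromid-like replicon (chromosome-like
#' composition, core genes, a plasmid-type rep1/rep2 cassette) and a
#' megaplasmid-like replicon (divergent composition, no core genes), so the
#' classifier can be exercised against every label.
#'
#' @inheritParams preset_embleya
#' @return List of \code{\link{replicon_spec}}s.
#' @export
preset_all_classes <- function(scale = 1) {
  base <- preset_embleya(scale)
  chr_mix <- base[[1L]]$cog_mixture
  pls_mix <- base[[3L]]$cog_mixture
  sec_tier <- c("genus-core" = 0.70, "strain-unique" = 0.15,
                "family-core" = 0.10, "universal" = 0.05)
  pls_tier <- c("strain-unique" = 0.85, "genus-core" = 0.10,
                "family-core" = 0.03, "universal" = 0.02)
  n <- function(x) max(4L, round(x * scale))
  c(base, list(
    replicon_spec("CHD", round(400000 * scale), "linear", 0.716,
                  gc_codon_weights(0.716), n_cds = n(150),
                  cog_mixture = chr_mix, marker_cassette = "plasmid",
                  tier_mixture = sec_tier, n_core_unique = 5L,
                  truth_label = "chromid"),
    replicon_spec("MPL", round(360000 * scale), "linear", 0.691,
                  gc_codon_weights(0.691), n_cds = n(120),
                  cog_mixture = pls_mix, tier_mixture = pls_tier,
                  truth_label = "megaplasmid")))
}

#' Closed-form expected statistics for a replicon spec
#'
#' Expectations usable as oracles: whole-replicon G+C, per-codon usage
#' percentages (with the forced start/stop correction at the mean CDS
#' length), TIR identity, COG category percentages, and per-tier expected
#' fA/fB and specificity score at each taxon level.
#'
#' @param spec A \code{\link{replicon_spec}}.
#' @param taxonomy,tier_presence As in \code{\link{generate_genome}}.
#' @param formula Specificity formula (see \code{\link{specificity_score}}).
#' @return List: \code{gc}, \code{codon_percent}, \code{tir_identity},
#'   \code{cog_percent}, \code{specificity} (data frame tier x level).
#' @export
predicted_statistics <- function(spec, taxonomy = default_taxonomy(),
                                 tier_presence = default_tier_presence(),
                                 formula = c("sq", "alt")) {
  formula <- match.arg(formula)
  w <- spec$codon_weights
  stops <- stop_codons()
  body_w <- w[setdiff(names(w), stops)]; body_w <- body_w / sum(body_w)
  stop_w <- w[stops]
  stop_w <- if (sum(stop_w) > 0) stop_w / sum(stop_w)
            else stats::setNames(rep(1 / 3, 3), stops)
  Lbar <- spec$cds_length_mean
  freq <- stats::setNames(numeric(64L), names(w))
  freq[names(body_w)] <- (Lbar - 2) * body_w
  freq["ATG"] <- freq["ATG"] + 1
  freq[stops] <- freq[stops] + stop_w
  freq <- freq / Lbar
  gcc <- vapply(strsplit(names(w), ""), function(ch) sum(ch %in% c("G", "C")),
                numeric(1))
  coding_gc <- sum(freq * gcc / 3)
  coding_frac <- min(1, 3 * spec$n_cds * Lbar / spec$length)
  tirlen <- if (is.null(spec$tir)) 0L else spec$tir$length
  tir_frac <- 2 * tirlen / spec$length
  # TIR bases are near-copies of target_gc background
  gc_exp <- coding_frac * coding_gc + (1 - coding_frac) * spec$target_gc
  tir_identity <- if (is.null(spec$tir)) NA_real_
                  else 100 * (1 - round(spec$tir$mutation_rate * tirlen) / tirlen)
  # expected COG percentages: second letters double-count categories but are
  # drawn from the same mixture, so percentages equal the mixture
  cog_percent <- 100 * spec$cog_mixture

  klass <- ifelse(taxonomy$genome_id == taxonomy$genome_id[1L], "focal",
           ifelse(taxonomy$genus == taxonomy$genus[1L], "genus",
           ifelse(taxonomy$family == taxonomy$family[1L], "family", "outgroup")))
  counts <- table(factor(klass, levels = c("focal", "genus", "family", "outgroup")))
  spec_rows <- list()
  for (tier in names(tier_presence)) {
    p <- tier_presence[[tier]]
    for (level in c("strain", "genus", "family")) {
      inA <- switch(level,
                    strain = c(focal = TRUE, genus = FALSE, family = FALSE, outgroup = FALSE),
                    genus = c(focal = TRUE, genus = TRUE, family = FALSE, outgroup = FALSE),
                    family = c(focal = TRUE, genus = TRUE, family = TRUE, outgroup = FALSE))
      pr <- c(focal = 1, genus = p[["genus"]], family = p[["family"]],
              outgroup = p[["outgroup"]])
      nA <- sum(counts[inA]); nB <- sum(counts[!inA])
      fA <- sum(counts[inA] * pr[names(counts)[inA]]) / nA
      fB <- sum(counts[!inA] * pr[names(counts)[!inA]]) / nB
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        tier = tier, level = level, fA = fA, fB = fB,
        score = specificity_score(fA, fB, formula))
    }
  }
  list(gc = gc_exp, codon_percent = 100 * freq, tir_identity = tir_identity,
       cog_percent = cog_percent, specificity = do.call(rbind, spec_rows))
}
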
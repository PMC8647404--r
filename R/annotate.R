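## Region and coding-effect vocabulary, ordered most to least severe.
## A variant hitting several transcripts reports its highest-severity call.
.SEVERITY <- c(
  "EXON_DELETED", "FRAME_SHIFT", "STOP_GAINED", "STOP_LOST", "START_LOST",
  "CODON_CHANGE_PLUS_CODON_INSERTION", "CODON_CHANGE_PLUS_CODON_DELETION",
  "CODON_INSERTION", "CODON_DELETION", "NON_SYNONYMOUS_CODING",
  "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR", "SPLICE_SITE_REGION",
  "SYNONYMOUS_CODING", "SYNONYMOUS_STOP", "INTRON", "UPSTREAM", "DOWNSTREAM",
  "INTRAGENIC", "INTERGENIC")

.CDS_EFFECTS <- c(
  "EXON_DELETED", "FRAME_SHIFT", "STOP_GAINED", "STOP_LOST", "START_LOST",
  "CODON_CHANGE_PLUS_CODON_INSERTION", "CODON_CHANGE_PLUS_CODON_DELETION",
  "CODON_INSERTION", "CODON_DELETION", "NON_SYNONYMOUS_CODING",
  "SYNONYMOUS_CODING", "SYNONYMOUS_STOP")

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

.translate_str <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Build a genome annotation from in-memory gene models
#'
#' Derives from gene/mRNA/exon/CDS features the interval sets the annotator
#' classifies against: introns (gaps between consecutive exons of a
#' transcript), strand-aware 5' upstream / 3' downstream flanks, splice
#' donor (first 2 intronic bases after an exon in transcript orientation),
#' splice acceptor (last 2 intronic bases before the next exon), and the
#' splice region (intronic bases 3-8 from either exon boundary plus the 3
#' exonic bases adjacent to each junction).
#'
#' @param features data.frame with columns chrom, type, start, end, strand,
#'   phase, ID, Parent (1-based closed coordinates, as in GFF3).
#' @param seq named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param flank_bp upstream/downstream flank size in bp.
#' @return a `genome_annotation` object.
#' @export
annotation_from_features <- function(features, seq, flank_bp = 5000L) {
  if (!inherits(seq, "DNAStringSet")) seq <- Biostrings::DNAStringSet(seq)
  f <- features
  gr <- function(rows)
    GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                           strand = rows$strand)
  genes_df <- f[f$type == "gene", , drop = FALSE]
  genes <- gr(genes_df)
  S4Vectors::mcols(genes)$gene_id <- genes_df$ID
  tx_df <- f[f$type == "mRNA", , drop = FALSE]
  exons_df <- f[f$type == "exon", , drop = FALSE]
  cds_df <- f[f$type == "CDS", , drop = FALSE]
  if (!all(cds_df$chrom %in% names(seq)))
    stop("CDS references a chromosome absent from the sequence set")
  exons <- gr(exons_df); S4Vectors::mcols(exons)$tx_id <- exons_df$Parent
  cds <- gr(cds_df)
  S4Vectors::mcols(cds)$tx_id <- cds_df$Parent
  S4Vectors::mcols(cds)$phase <- cds_df$phase

  introns <- donor <- acceptor <- region <- list()
  bad_tx <- character(0)
  for (t in tx_df$ID) {
    ex <- exons_df[exons_df$Parent == t, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]
    cl <- sum(cds_df$end[cds_df$Parent == t] - cds_df$start[cds_df$Parent == t] + 1L)
    if (cl %% 3L != 0L) {
      warning("CDS length of ", t, " not divisible by 3; transcript flagged")
      bad_tx <- c(bad_tx, t)
    }
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      is_ <- ex$end[i] + 1L; ie <- ex$start[i + 1L] - 1L
      if (is_ > ie) next
      introns[[length(introns) + 1L]] <- data.frame(
        chrom = chrom, start = is_, end = ie, strand = strand, tx_id = t)
      ## donor at the transcript-5' end of the intron, acceptor at its 3' end
      left2 <- c(is_, min(is_ + 1L, ie)); right2 <- c(max(ie - 1L, is_), ie)
      if (strand == "+") {
        donor[[length(donor) + 1L]] <- data.frame(
          chrom = chrom, start = left2[1], end = left2[2], strand = strand, tx_id = t)
        acceptor[[length(acceptor) + 1L]] <- data.frame(
          chrom = chrom, start = right2[1], end = right2[2], strand = strand, tx_id = t)
      } else {
        donor[[length(donor) + 1L]] <- data.frame(
          chrom = chrom, start = right2[1], end = right2[2], strand = strand, tx_id = t)
        acceptor[[length(acceptor) + 1L]] <- data.frame(
          chrom = chrom, start = left2[1], end = left2[2], strand = strand, tx_id = t)
      }
      ## intronic splice region: bases 3-8 from each intron end
      if (ie - is_ + 1L > 2L) {
        region[[length(region) + 1L]] <- data.frame(
          chrom = chrom, start = is_ + 2L, end = min(is_ + 7L, ie),
          strand = strand, tx_id = t)
        region[[length(region) + 1L]] <- data.frame(
          chrom = chrom, start = max(ie - 7L, is_), end = ie - 2L,
          strand = strand, tx_id = t)
      }
      ## exonic splice region: 3 exonic bases adjacent to the junction
      region[[length(region) + 1L]] <- data.frame(
        chrom = chrom, start = max(ex$start[i], ex$end[i] - 2L), end = ex$end[i],
        strand = strand, tx_id = t)
      region[[length(region) + 1L]] <- data.frame(
        chrom = chrom, start = ex$start[i + 1L],
        end = min(ex$end[i + 1L], ex$start[i + 1L] + 2L),
        strand = strand, tx_id = t)
    }
  }
  bind_gr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    d <- do.call(rbind, lst)
    g <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                                strand = d$strand)
    S4Vectors::mcols(g)$tx_id <- d$tx_id
    g
  }
  ## strand-aware flanks, clipped to chromosome bounds
  chrlen <- stats::setNames(Biostrings::width(seq), names(seq))
  up <- dn <- genes_df
  if (nrow(genes_df)) {
    plus <- genes_df$strand == "+"
    up$start <- ifelse(plus, pmax(1L, genes_df$start - flank_bp), genes_df$end + 1L)
    up$end <- ifelse(plus, genes_df$start - 1L,
                     pmin(chrlen[genes_df$chrom], genes_df$end + flank_bp))
    dn$start <- ifelse(plus, genes_df$end + 1L,
                       pmax(1L, genes_df$start - flank_bp))
    dn$end <- ifelse(plus, pmin(chrlen[genes_df$chrom], genes_df$end + flank_bp),
                     genes_df$start - 1L)
  }
  flank_gr <- function(d) {
    keep <- d$start <= d$end
    g <- GenomicRanges::GRanges(d$chrom[keep],
                                IRanges::IRanges(d$start[keep], d$end[keep]),
                                strand = d$strand[keep])
    S4Vectors::mcols(g)$gene_id <- d$ID[keep]
    g
  }
  structure(list(
    genes = genes, transcripts = tx_df[, c("ID", "Parent", "chrom", "strand")],
    exons = exons, cds = cds, introns = bind_gr(introns),
    splice_donor = bind_gr(donor), splice_acceptor = bind_gr(acceptor),
    splice_region = bind_gr(region), upstream = flank_gr(up),
    downstream = flank_gr(dn), seq = seq, flank_bp = flank_bp,
    flagged_tx = bad_tx), class = "genome_annotation")
}

#' Load a genome annotation from GFF3 and FASTA files
#'
#' @param gff3_path GFF3 with gene/mRNA/exon/CDS features.
#' @param fasta_path reference FASTA covering all annotated chromosomes.
#' @param flank_bp upstream/downstream flank size in bp.
#' @return a `genome_annotation`; see [annotation_from_features()].
#' @export
load_annotation <- function(gff3_path, fasta_path, flank_bp = 5000L) {
  g <- rtracklayer::import(gff3_path, format = "gff3")
  m <- S4Vectors::mcols(g)
  parent <- vapply(as.list(m$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  features <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(g)),
    type = as.character(m$type),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    phase = if ("phase" %in% colnames(m)) as.integer(m$phase) else NA_integer_,
    ID = as.character(m$ID), Parent = parent)
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*", "", names(seq))
  annotation_from_features(features, seq, flank_bp)
}

## Per-transcript CDS geometry: pieces in transcript order, the spliced CDS
## sequence on the coding strand, and a genome -> CDS coordinate map.
.tx_cds_info <- function(ann, tx, chrom_seq = NULL) {
  p <- ann$cds[S4Vectors::mcols(ann$cds)$tx_id == tx]
  p <- p[order(GenomicRanges::start(p))]
  strand <- as.character(GenomicRanges::strand(p))[1]
  chrom <- as.character(GenomicRanges::seqnames(p))[1]
  tx_order <- if (strand == "+") seq_along(p) else rev(seq_along(p))
  if (is.null(chrom_seq)) chrom_seq <- as.character(ann$seq[[chrom]])
  ## ascending-genome concatenation; reverse-complementing the whole string
  ## yields transcript order for minus-strand CDS
  pieces <- paste(substring(chrom_seq, GenomicRanges::start(p),
                            GenomicRanges::end(p)), collapse = "")
  cds_seq <- if (strand == "+") pieces else .revcomp(pieces)
  starts <- GenomicRanges::start(p); ends <- GenomicRanges::end(p)
  widths <- ends - starts + 1L
  cum_before <- c(0L, cumsum(widths[tx_order]))[seq_along(p)]
  g2c <- function(pos) {  # genome position -> 1-based CDS coordinate (or NA)
    for (j in seq_along(tx_order)) {
      i <- tx_order[j]
      if (pos >= starts[i] && pos <= ends[i]) {
        off <- if (strand == "+") pos - starts[i] else ends[i] - pos
        return(cum_before[j] + off + 1L)
      }
    }
    NA_integer_
  }
  list(chrom = chrom, strand = strand, starts = starts, ends = ends,
       cds_seq = cds_seq, g2c = g2c, n = nchar(cds_seq))
}

## Coding effect of a SNP on one transcript (NA if not in its CDS)
.snp_cds_effect <- function(info, pos, alt) {
  cpos <- info$g2c(pos)
  if (is.na(cpos)) return(NA_character_)
  alt_c <- if (info$strand == "+") alt else .revcomp(alt)
  ci <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  old <- substr(info$cds_seq, 3L * ci + 1L, 3L * ci + 3L)
  new <- old
  substr(new, within, within) <- alt_c
  aa_old <- Biostrings::GENETIC_CODE[old]
  aa_new <- Biostrings::GENETIC_CODE[new]
  if (ci == 0L && old == "ATG" && aa_new != "M") return("START_LOST")
  if (aa_old == aa_new)
    return(if (aa_old == "*") "SYNONYMOUS_STOP" else "SYNONYMOUS_CODING")
  if (aa_new == "*") return("STOP_GAINED")
  if (aa_old == "*") return("STOP_LOST")
  "NON_SYNONYMOUS_CODING"
}

## Coding effect of a left-normalized InDel on one transcript
.indel_cds_effect <- function(info, pos, ref, alt) {
  is_del <- nchar(ref) > nchar(alt)
  if (is_del) {
    del_start <- pos + 1L; del_end <- pos + nchar(ref) - 1L
    ## deletion wiping out a whole CDS exon
    if (any(info$starts >= del_start & info$ends <= del_end))
      return("EXON_DELETED")
    hit <- which(info$ends >= del_start & info$starts <= del_end)
    if (!length(hit)) return(NA_character_)
    del_pos <- unlist(lapply(hit, function(i)
      max(del_start, info$starts[i]):min(del_end, info$ends[i])))
    cpos <- sort(vapply(del_pos, info$g2c, integer(1)))
    if (length(cpos) %% 3L != 0L) return("FRAME_SHIFT")
    aligned <- (cpos[1] - 1L) %% 3L == 0L
    base <- if (aligned) "CODON_DELETION" else "CODON_CHANGE_PLUS_CODON_DELETION"
    keep <- setdiff(seq_len(info$n), cpos)
    new_cds <- paste(strsplit(info$cds_seq, "")[[1]][keep], collapse = "")
    .stop_override(info$cds_seq, new_cds, base)
  } else {
    cpos <- info$g2c(pos)
    if (is.na(cpos)) return(NA_character_)
    ins <- substr(alt, 2L, nchar(alt))
    if (info$strand == "-") ins <- .revcomp(ins)
    ins_after <- if (info$strand == "+") cpos else cpos - 1L
    if (nchar(ins) %% 3L != 0L) return("FRAME_SHIFT")
    aligned <- ins_after %% 3L == 0L
    base <- if (aligned) "CODON_INSERTION" else "CODON_CHANGE_PLUS_CODON_INSERTION"
    new_cds <- paste0(substr(info$cds_seq, 1L, ins_after), ins,
                      substr(info$cds_seq, ins_after + 1L, info$n))
    .stop_override(info$cds_seq, new_cds, base)
  }
}

## In-frame InDels: creation of a premature stop overrides to STOP_GAINED,
## loss of the terminal stop overrides to STOP_LOST.
.stop_override <- function(old_cds, new_cds, base) {
  aa_old <- .translate_str(old_cds)
  aa_new <- .translate_str(new_cds)
  interior_stop <- function(aa) grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
  if (interior_stop(aa_new) && !interior_stop(aa_old)) return("STOP_GAINED")
  if (grepl("\\*$", aa_old) && !grepl("\\*", aa_new)) return("STOP_LOST")
  base
}

## Left-normalize an InDel against the reference (shift left while the
## trailing bases of both alleles match the base preceding the locus).
.left_normalize <- function(chrom_seq, pos, ref, alt) {
  while (pos > 1L && nchar(ref) != nchar(alt) &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    prev <- substr(chrom_seq, pos - 1L, pos - 1L)
    ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
    alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

## Batch annotation engine. sites: data.frame(chrom, pos, ref, alt).
## One label per variant: candidates from every overlapping feature set,
## ranked by the fixed severity order.
.annotate_core <- function(sites, ann) {
  n <- nrow(sites)
  chrom_seqs <- lapply(seq_along(ann$seq), function(i) as.character(ann$seq[[i]]))
  names(chrom_seqs) <- names(ann$seq)
  if (!all(sites$chrom %in% names(ann$seq)))
    stop("variant on unannotated chromosome: ",
         sites$chrom[!sites$chrom %in% names(ann$seq)][1])
  pos <- sites$pos; ref <- sites$ref; alt <- sites$alt
  chrlen <- stats::setNames(Biostrings::width(ann$seq), names(ann$seq))
  if (any(pos + nchar(ref) - 1L > chrlen[sites$chrom]))
    stop("variant beyond chromosome end")
  for (i in which(nchar(ref) != nchar(alt))) {
    nm <- .left_normalize(chrom_seqs[[sites$chrom[i]]], pos[i], ref[i], alt[i])
    pos[i] <- nm$pos; ref[i] <- nm$ref; alt[i] <- nm$alt
  }
  foot <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(pos, pos + nchar(ref) - 1L))
  cand <- lapply(seq_len(n), function(i) character(0))
  cand_tx <- lapply(seq_len(n), function(i) character(0))
  add <- function(i, lab, tx) {
    cand[[i]] <<- c(cand[[i]], lab)
    cand_tx[[i]] <<- c(cand_tx[[i]], tx)
  }
  ## CDS effects per overlapping transcript, with cached CDS geometry
  ov <- GenomicRanges::findOverlaps(foot, ann$cds, ignore.strand = TRUE)
  tx_hit <- S4Vectors::mcols(ann$cds)$tx_id[S4Vectors::subjectHits(ov)]
  q_hit <- S4Vectors::queryHits(ov)
  tx_cache <- new.env(parent = emptyenv())
  for (r in which(!duplicated(paste(q_hit, tx_hit)))) {
    i <- q_hit[r]; tx <- tx_hit[r]
    info <- tx_cache[[tx]]
    if (is.null(info)) {
      info <- .tx_cds_info(ann, tx, chrom_seqs[[sites$chrom[i]]])
      tx_cache[[tx]] <- info
    }
    eff <- if (nchar(ref[i]) == nchar(alt[i])) .snp_cds_effect(info, pos[i], alt[i])
           else .indel_cds_effect(info, pos[i], ref[i], alt[i])
    if (!is.na(eff)) add(i, eff, tx)
  }
  sets <- list(splice_donor = "SPLICE_SITE_DONOR",
               splice_acceptor = "SPLICE_SITE_ACCEPTOR",
               splice_region = "SPLICE_SITE_REGION",
               introns = "INTRON")
  for (nm in names(sets)) {
    gr <- ann[[nm]]
    ov <- GenomicRanges::findOverlaps(foot, gr, ignore.strand = TRUE)
    for (r in which(!duplicated(S4Vectors::queryHits(ov)))) {
      i <- S4Vectors::queryHits(ov)[r]
      add(i, sets[[nm]], S4Vectors::mcols(gr)$tx_id[S4Vectors::subjectHits(ov)[r]])
    }
  }
  gsets <- list(genes = "INTRAGENIC", upstream = "UPSTREAM",
                downstream = "DOWNSTREAM")
  for (nm in names(gsets)) {
    gr <- ann[[nm]]
    ov <- GenomicRanges::findOverlaps(foot, gr, ignore.strand = TRUE)
    for (r in which(!duplicated(S4Vectors::queryHits(ov)))) {
      i <- S4Vectors::queryHits(ov)[r]
      add(i, gsets[[nm]], S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(ov)[r]])
    }
  }
  label <- character(n); tx_best <- character(n)
  for (i in seq_len(n)) {
    if (!length(cand[[i]])) { label[i] <- "INTERGENIC"; tx_best[i] <- NA; next }
    b <- which.min(match(cand[[i]], .SEVERITY))
    label[i] <- cand[[i]][b]; tx_best[i] <- cand_tx[[i]][b]
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt,
             class = .variant_class(sites$ref, sites$alt),
             region = ifelse(label %in% .CDS_EFFECTS, "CDS", label),
             cds_effect = ifelse(label %in% .CDS_EFFECTS, label, NA_character_),
             transcript = tx_best, label = label)
}

#' Annotate one variant against the genome annotation
#'
#' The genomic region is chosen by precedence CDS > splice donor/acceptor >
#' splice region > intron > intragenic > upstream/downstream > intergenic,
#' and for CDS variants a coding effect is derived on the coding strand
#' with the standard genetic code: a mutated codon translating to the same
#' amino acid is SYNONYMOUS_CODING (SYNONYMOUS_STOP when it was and remains
#' a stop), a new stop is STOP_GAINED, a lost stop STOP_LOST, a destroyed
#' initial ATG START_LOST, anything else NON_SYNONYMOUS_CODING; CDS InDels
#' are FRAME_SHIFT when their length is not a multiple of 3, otherwise
#' CODON_INSERTION / CODON_DELETION when codon-aligned (after
#' left-normalization) and CODON_CHANGE_PLUS_CODON_INSERTION / _DELETION
#' when not, with stop creation/removal overriding to STOP_GAINED /
#' STOP_LOST and a deletion spanning a whole exon reported as EXON_DELETED.
#' Across multiple overlapping transcripts the highest-severity call is
#' reported.
#'
#' @param chrom,pos,ref,alt the variant (VCF conventions, 1-based pos).
#' @param ann a `genome_annotation`.
#' @return list with `region` (one of INTERGENIC, INTRAGENIC, INTRON,
#'   UPSTREAM, DOWNSTREAM, SPLICE_SITE_ACCEPTOR, SPLICE_SITE_DONOR,
#'   SPLICE_SITE_REGION, CDS), `cds_effect` (NA unless region == "CDS"),
#'   `transcript` and the ranked `label`.
#' @export
annotate_variant <- function(chrom, pos, ref, alt, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  row <- .annotate_core(data.frame(chrom = chrom, pos = pos, ref = ref,
                                   alt = alt), ann)
  list(region = row$region, cds_effect = row$cds_effect,
       transcript = row$transcript, label = row$label)
}

#' Annotate every variant of a variant set
#'
#' Batch version of [annotate_variant()].
#'
#' @param vs a `variant_set`.
#' @param ann a `genome_annotation`.
#' @return data.frame: chrom, pos, ref, alt, class, region, cds_effect,
#'   transcript, label (one row per variant).
#' @export
annotate_variants <- function(vs, ann) {
  stopifnot(inherits(vs, "variant_set"), inherits(ann, "genome_annotation"))
  .annotate_core(vs$sites[, c("chrom", "pos", "ref", "alt")], ann)
}

#' Tabulate effect calls into the standard annotation count table
#'
#' Rows are ordered with the plain genomic regions first and the CDS coding
#' effects after, all categories always present (zero counts kept), so the
#' counts partition the input calls.
#'
#' @param calls output of [annotate_variants()].
#' @return data.frame: region ("-" or "CDS"), type, count.
#' @export
effect_table <- function(calls) {
  regions <- c("INTERGENIC", "INTRAGENIC", "INTRON", "UPSTREAM", "DOWNSTREAM",
               "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR", "SPLICE_SITE_REGION")
  cds_types <- c("START_LOST", "SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING",
                 "SYNONYMOUS_STOP", "STOP_GAINED", "STOP_LOST", "FRAME_SHIFT",
                 "CODON_INSERTION", "EXON_DELETED", "CODON_DELETION",
                 "CODON_CHANGE_PLUS_CODON_DELETION",
                 "CODON_CHANGE_PLUS_CODON_INSERTION")
  data.frame(
    region = c(rep("-", length(regions)), rep("CDS", length(cds_types))),
    type = c(regions, cds_types),
    count = vapply(c(regions, cds_types), function(t)
      sum(calls$label == t), integer(1)),
    row.names = NULL)
}
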
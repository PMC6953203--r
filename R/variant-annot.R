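# Variant-consequence annotation against simple gene models, protein-change
# notation, and amplicon haplotype grouping.

#' Build a gene model
#'
#' A minimal gene model for variant annotation: ordered exons, a CDS span and
#' the genomic reference sequence of the locus. The spliced CDS must be a
#' multiple of three, begin with ATG and end with a stop codon (checked in
#' reading-strand orientation).
#'
#' @param gene_id Gene identifier.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates), non-overlapping and sorted.
#' @param cds_start,cds_end Genomic span of the coding sequence.
#' @param seq Reference genomic sequence covering the model (character).
#' @param seq_start Genomic coordinate of the first base of `seq`. Default 1.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome label. Default `NA`.
#' @return An `anthomap_gene_model` list.
#' @export
gene_model <- function(gene_id, exons, cds_start, cds_end, seq,
                       seq_start = 1L, strand = c("+", "-"),
                       chrom = NA_integer_) {
  strand <- match.arg(strand)
  exons <- as_tibble(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    abort("`exons` needs columns start and end")
  }
  if (any(exons$end < exons$start)) abort("exon end before start")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(utils::head(exons$end, -1) >= utils::tail(exons$start, -1))) {
    abort("exons must be sorted and non-overlapping")
  }
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) abort("reference sequence must be A/C/G/T/N")
  model <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand, exons = exons,
         cds_start = cds_start, cds_end = cds_end, seq = seq,
         seq_start = as.integer(seq_start)),
    class = "anthomap_gene_model"
  )
  cds <- spliced_cds(model)
  if (nchar(cds) %% 3 != 0) abort("spliced CDS length is not a multiple of 3")
  if (substr(cds, 1, 3) != "ATG") abort("CDS does not begin with ATG")
  if (!substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    abort("CDS does not end with a stop codon")
  }
  model
}

#' @export
print.anthomap_gene_model <- function(x, ...) {
  cat("<anthomap_gene_model>", x$gene_id, sprintf("(%s strand)", x$strand),
      "-", nrow(x$exons), "exons, CDS", x$cds_start, "-", x$cds_end, "\n")
  invisible(x)
}

ref_base <- function(model, pos, n = 1L) {
  i <- pos - model$seq_start + 1L
  if (i < 1 || i + n - 1L > nchar(model$seq)) abort("position outside the model sequence")
  substr(model$seq, i, i + n - 1L)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Genomic positions (ascending) of the CDS bases.
cds_positions <- function(model) {
  pos <- unlist(purrr::pmap(model$exons, function(start, end) {
    s <- max(start, model$cds_start)
    e <- min(end, model$cds_end)
    if (s > e) integer(0) else s:e
  }))
  sort(pos)
}

# Spliced CDS in reading-strand orientation.
spliced_cds <- function(model) {
  pos <- cds_positions(model)
  s <- paste(vapply(pos, function(p) ref_base(model, p), ""), collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

translate_dna <- function(s) {
  s <- substr(s, 1, nchar(s) %/% 3 * 3)
  if (nchar(s) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

# VCF-style normalization: trim shared suffix then prefix (advancing pos),
# then left-align against the reference.
normalize_variant <- function(model, pos, ref, alt) {
  repeat {
    changed <- FALSE
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      changed <- TRUE
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    # left shift an anchored indel while the preceding reference base equals
    # the last base of both alleles
    if (nchar(ref) != nchar(alt) && min(nchar(ref), nchar(alt)) == 1 &&
        pos > model$seq_start &&
        substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      prev <- ref_base(model, pos - 1L)
      ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
      alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Annotate a variant against a gene model
#'
#' Classifies a SNV or indel (VCF convention: indels anchored at the base
#' before the event) by its overlap with the coding sequence, introns and the
#' upstream promoter window. Coding SNVs are translated and reported as
#' residue-numbered substitutions (e.g. `C42Y`); coding indels are classified
#' by length modulo 3 (frameshift vs in-frame); indels in the promoter window
#' are reported with a negative offset where the base 5' of the A of ATG is
#' -1. Intronic variants within 2 bases of an exon boundary are
#' `splice_adjacent`.
#'
#' @param model An [gene_model()].
#' @param pos 1-based genomic position of the variant.
#' @param ref,alt Reference and alternate allele strings.
#' @param promoter_window Upstream window in bp. Default 2000.
#' @return One-row tibble: `gene_id`, `pos`, `ref`, `alt`, `category`,
#'   `protein_change`, `promoter_offset`.
#' @examples
#' m <- gene_model("g", data.frame(start = 101, end = 130), 101, 130,
#'   seq = paste0(strrep("A", 100), "ATGTGCTGGAAAGTTGATCCCGGGTCATAA"),
#'   seq_start = 1)
#' annotate_variant(m, 106, "G", "A") # missense C2Y
#' @export
annotate_variant <- function(model, pos, ref, alt, promoter_window = 2000) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (promoter_window < 0) abort("`promoter_window` must be >= 0")
  observed <- ref_base(model, pos, nchar(ref))
  if (observed != ref) {
    abort(sprintf("reference mismatch at %d: expected %s, reference has %s",
                  pos, ref, observed))
  }
  v <- normalize_variant(model, pos, ref, alt)
  pos <- v$pos; ref <- v$ref; alt <- v$alt
  is_indel <- nchar(ref) != nchar(alt)
  cds_pos <- cds_positions(model)
  exonic <- function(p) any(model$exons$start <= p & p <= model$exons$end)
  gene_span <- c(min(model$exons$start), max(model$exons$end))

  # genomic bases altered by the event
  affected <- if (!is_indel) {
    pos:(pos + nchar(ref) - 1L)
  } else if (nchar(ref) > nchar(alt)) {
    (pos + 1L):(pos + nchar(ref) - 1L) # deletion
  } else {
    # insertion between pos and pos + 1
    c(pos, pos + 1L)
  }

  out <- function(category, protein_change = NA_character_,
                  promoter_offset = NA_integer_) {
    tibble(gene_id = model$gene_id, pos = pos, ref = ref, alt = alt,
           category = category, protein_change = protein_change,
           promoter_offset = promoter_offset)
  }

  if (is_indel) {
    hits_cds <- if (nchar(ref) > nchar(alt)) {
      any(affected %in% cds_pos)
    } else {
      all(affected %in% cds_pos) # insertion strictly inside coding exon
    }
    if (hits_cds) {
      shift <- abs(nchar(ref) - nchar(alt)) %% 3
      if (shift != 0) {
        # first CDS base touched by the event locates the residue where the
        # frame changes
        hit <- affected[affected %in% cds_pos]
        k_plus <- match(if (length(hit)) hit[1] else affected[1], cds_pos)
        k <- if (model$strand == "-") length(cds_pos) - k_plus + 1L else k_plus
        codon <- ceiling(k / 3)
        ref_aa <- strsplit(translate_dna(spliced_cds(model)), "")[[1]]
        return(out("frameshift",
                   protein_change = sprintf("%s%dfs", ref_aa[codon], codon)))
      }
      return(out("inframe_indel"))
    }
  }

  in_cds <- !is_indel && all(affected %in% cds_pos)
  if (in_cds) {
    ref_cds <- spliced_cds(model)
    alt_cds <- mutated_cds(model, pos, ref, alt)
    chg <- protein_change(ref_cds, alt_cds)
    cat_ <- if (length(chg) == 0) "synonymous" else "missense"
    return(out(cat_, protein_change = if (length(chg)) paste(chg, collapse = ";") else NA_character_))
  }

  # upstream promoter window, measured from the A of ATG (-1 = adjacent base).
  # An insertion belongs to the side of its anchor base, so an insertion
  # between the ATG and the base before it is promoter, not coding.
  is_insertion <- is_indel && nchar(alt) > nchar(ref)
  affected_loc <- if (is_insertion) pos else affected
  offset <- if (model$strand == "+") pos - model$cds_start else model$cds_end - pos
  if (offset < 0 && offset >= -promoter_window &&
      !any(affected_loc >= gene_span[1] & affected_loc <= gene_span[2] &
             sapply(affected_loc, exonic))) {
    if (is_indel) return(out("promoter_indel", promoter_offset = as.integer(offset)))
    return(out("intergenic", promoter_offset = as.integer(offset)))
  }

  intronic <- any(affected >= gene_span[1] & affected <= gene_span[2] &
                    !sapply(affected, exonic))
  if (intronic) {
    bounds <- c(model$exons$start - 1L, model$exons$end + 1L)
    near <- any(vapply(affected, function(p) any(abs(p - bounds) <= 1L), TRUE))
    return(out(if (near) "splice_adjacent" else "intronic"))
  }
  out("intergenic")
}

# Apply a variant to the model's spliced CDS (reading-strand orientation).
mutated_cds <- function(model, pos, ref, alt) {
  gseq <- model$seq
  i <- pos - model$seq_start + 1L
  mut <- paste0(substr(gseq, 1, i - 1L), alt,
                substr(gseq, i + nchar(ref), nchar(gseq)))
  # re-extract CDS bases, accounting for the length change downstream of pos
  delta <- nchar(alt) - nchar(ref)
  pieces <- purrr::pmap_chr(model$exons, function(start, end) {
    s <- max(start, model$cds_start)
    e <- min(end, model$cds_end)
    if (s > e) return("")
    # positions after the event slide by delta in the mutated string
    si <- s - model$seq_start + 1L + if (s > pos) delta else 0L
    ei <- e - model$seq_start + 1L + if (e > pos) delta else 0L
    substr(mut, si, ei)
  })
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

#' Protein-level change between two coding sequences
#'
#' Translates both sequences with the standard genetic code and reports each
#' differing residue as `<refAA><position><altAA>`. A length change that is
#' not a multiple of three is reported as a frameshift descriptor
#' `<refAA><position>fs` at the first affected residue.
#'
#' @param ref_cds,alt_cds Nucleotide strings (the reference CDS must begin
#'   with ATG).
#' @return Character vector of change notations; empty when the proteins are
#'   identical.
#' @examples
#' protein_change("ATGTGCTAA", "ATGTACTAA") # "C2Y"
#' @export
protein_change <- function(ref_cds, alt_cds) {
  ref_cds <- toupper(ref_cds); alt_cds <- toupper(alt_cds)
  if (!grepl("^[ACGT]*$", ref_cds) || !grepl("^[ACGT]*$", alt_cds)) {
    abort("coding sequences must contain only A/C/G/T")
  }
  ref_aa <- strsplit(translate_dna(ref_cds), "")[[1]]
  alt_aa <- strsplit(translate_dna(alt_cds), "")[[1]]
  if ((nchar(ref_cds) - nchar(alt_cds)) %% 3 != 0) {
    n <- min(length(ref_aa), length(alt_aa))
    k <- which(ref_aa[seq_len(n)] != alt_aa[seq_len(n)])
    first <- if (length(k)) k[1] else n + 1L
    first <- min(first, length(ref_aa))
    return(sprintf("%s%dfs", ref_aa[first], first))
  }
  n <- min(length(ref_aa), length(alt_aa))
  k <- which(ref_aa[seq_len(n)] != alt_aa[seq_len(n)])
  sprintf("%s%d%s", ref_aa[k], k, alt_aa[k])
}

#' Group amplicon haplotypes by exact sequence identity
#'
#' Sanger-sequenced amplicons are grouped by exact comparison after
#' uppercasing: two groups differ by at least one substitution or indel.
#' A sequence containing IUPAC ambiguity codes (double peaks from direct
#' sequencing) flags its genotype as carrying multiple homologs.
#'
#' @param data Data frame with columns `genotype` and `sequence`.
#' @return Tibble `genotype`, `sequence`, `group` (integer), `multi_homolog`;
#'   the number of groups is attached as attribute `n_groups`.
#' @examples
#' group_haplotypes(data.frame(
#'   genotype = c("a", "b", "c"),
#'   sequence = c("ACGT", "ACGT", "ACGA")))
#' @export
group_haplotypes <- function(data) {
  if (!all(c("genotype", "sequence") %in% names(data))) {
    abort("`data` needs columns genotype and sequence")
  }
  if (nrow(data) == 0) abort("no sequences to group")
  seqs <- toupper(data$sequence)
  if (!all(grepl("^[ACGTURYSWKMBDHVN-]*$", seqs))) {
    abort("sequences must be over the IUPAC alphabet")
  }
  out <- tibble(
    genotype = data$genotype,
    sequence = seqs,
    group = match(seqs, unique(seqs)),
    multi_homolog = grepl("[RYSWKMBDHVN]", seqs)
  )
  structure(out, n_groups = length(unique(out$group)))
}
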
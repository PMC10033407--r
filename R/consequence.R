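#' Transcript models
#'
#' A transcript model holds the exon and CDS structure of one transcript as
#' 1-based closed genomic intervals. Exons must be sorted and non-overlapping
#' and every CDS interval must lie within an exon.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons,cds data.frames with columns start, end (cds may have 0 rows
#'   for non-coding transcripts).
#' @param biotype transcript biotype (default "protein_coding").
#' @param canonical logical; canonical-transcript status is an input, never
#'   computed.
#' @return an object of class "transcript_model".
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = exons[0, ], biotype = "protein_coding",
                             canonical = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end"), drop = FALSE]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in ", transcript_id)
  if (nrow(cds) > 0) {
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside)) stop("CDS outside exons in ", transcript_id)
    if (sum(cds$end - cds$start + 1) < 3)
      stop("coding transcript ", transcript_id, " has CDS shorter than one codon")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds, biotype = biotype,
                 canonical = isTRUE(canonical)),
            class = "transcript_model")
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (plain text).
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read transcript models from a GTF file
#'
#' Uses exon and CDS features; gene_id, transcript_id and (when present)
#' biotype and a "canonical" attribute are taken from the attribute column.
#'
#' @param path GTF file.
#' @return list of [transcript_model()] objects, named by transcript id.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), ]
  if (nrow(df) == 0) return(list())
  bt <- if ("transcript_biotype" %in% names(df)) df$transcript_biotype
        else if ("gene_biotype" %in% names(df)) df$gene_biotype
        else rep("protein_coding", nrow(df))
  df$._biotype <- ifelse(is.na(bt), "protein_coding", bt)
  df$._canonical <- if ("canonical" %in% names(df)) {
    !is.na(df$canonical) & df$canonical %in% c("1", "TRUE", "true")
  } else TRUE
  split_tx <- split(df, df$transcript_id)
  out <- lapply(split_tx, function(d) {
    transcript_model(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = sub("^chr", "", as.character(d$seqnames[1])),
      strand = as.character(d$strand[1]),
      exons = d[d$type == "exon", c("start", "end")],
      cds = d[d$type == "CDS", c("start", "end")],
      biotype = d$._biotype[1], canonical = d$._canonical[1])
  })
  out[order(names(out))]
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  if (nchar(s) == 0) return(s)
  paste(rev(REVCOMP[strsplit(s, "")[[1]]]), collapse = "")
}

genome_seq <- function(genome, chrom, start, end) {
  s <- genome[[as.character(chrom)]]
  if (is.null(s)) stop("chromosome ", chrom, " absent from genome")
  if (start < 1 || end > nchar(s)) stop("coordinates outside chromosome ", chrom)
  substr(s, start, end)
}

# Splice windows: the first 2 intronic bases after an exon in transcript
# orientation are the donor site, the last 2 before an exon the acceptor.
splice_windows <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(list(donor = ex[0, ], acceptor = ex[0, ]))
  istart <- ex$end[-nrow(ex)] + 1
  iend <- ex$start[-1] - 1
  keep <- iend >= istart
  istart <- istart[keep]; iend <- iend[keep]
  left <- data.frame(start = istart, end = pmin(istart + 1, iend))
  right <- data.frame(start = pmax(iend - 1, istart), end = iend)
  if (tx$strand == "+") list(donor = left, acceptor = right)
  else list(donor = right, acceptor = left)
}

in_intervals <- function(b, iv) {
  if (nrow(iv) == 0) return(FALSE)
  any(b >= iv$start & b <= iv$end)
}

# 1-based CDS coordinate of genomic base b in transcript orientation,
# or NA when b is not coding.
cds_coord <- function(tx, b) {
  cds <- tx$cds
  if (nrow(cds) == 0 || !in_intervals(b, cds)) return(NA_integer_)
  lens <- cds$end - cds$start + 1
  if (tx$strand == "+") {
    i <- which(b >= cds$start & b <= cds$end)
    before <- if (i > 1) sum(lens[seq_len(i - 1)]) else 0
    before + (b - cds$start[i] + 1)
  } else {
    i <- which(b >= cds$start & b <= cds$end)
    after <- if (i < nrow(cds)) sum(lens[seq(i + 1, nrow(cds))]) else 0
    after + (cds$end[i] - b + 1)
  }
}

cds_sequence <- function(tx, genome) {
  pieces <- vapply(seq_len(nrow(tx$cds)), function(i) {
    genome_seq(genome, tx$chrom, tx$cds$start[i], tx$cds$end[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Assign Sequence Ontology consequence terms to a variant on a transcript
#'
#' Classifies a normalized variant against one transcript model: UTR and
#' intron terms for non-coding positions, splice donor/acceptor terms for the
#' two intronic bases flanking exons (in transcript orientation), and for CDS
#' positions codon-level terms for SNVs (synonymous, missense, stop_gained,
#' stop_lost, start_lost) or length-based terms for indels (frameshift when
#' the net length change is not a multiple of three, in-frame insertion or
#' deletion otherwise). An indel that spans an exon-intron boundary is classed
#' by its splice/intron overlap only (the more severe rule wins). Variants at
#' the stop codon that produce a different stop codon are synonymous.
#'
#' @param chrom,pos,ref,alt one normalized variant (ref or alt may be "").
#' @param tx a [transcript_model()].
#' @param genome named character vector of chromosome sequences.
#' @return character vector of SO terms (empty when the variant does not
#'   interact with the transcript).
#' @export
assign_consequences <- function(chrom, pos, ref, alt, tx, genome) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (chrom != tx$chrom) return(character(0))
  ref <- toupper(ref); alt <- toupper(alt)
  rlen <- nchar(ref); alen <- nchar(alt)
  if (rlen > 0) {
    obs <- genome_seq(genome, chrom, pos, pos + rlen - 1)
    if (obs != ref) {
      stop("reference mismatch at ", chrom, ":", pos, " (expected ", ref,
           ", genome has ", obs, ")")
    }
  }
  span_lo <- min(tx$exons$start); span_hi <- max(tx$exons$end)
  bases <- if (rlen > 0) seq(pos, pos + rlen - 1) else c(pos - 1, pos)
  bases <- bases[bases >= span_lo & bases <= span_hi]
  if (length(bases) == 0) return(character(0))

  sw <- splice_windows(tx)
  terms <- character(0)
  cds_hit <- FALSE
  intronic_hit <- FALSE
  for (b in bases) {
    if (in_intervals(b, sw$donor)) { terms <- c(terms, "splice_donor_variant"); intronic_hit <- TRUE }
    else if (in_intervals(b, sw$acceptor)) { terms <- c(terms, "splice_acceptor_variant"); intronic_hit <- TRUE }
    else if (!in_intervals(b, tx$exons)) { terms <- c(terms, "intron_variant"); intronic_hit <- TRUE }
    else if (!is.na(cds_coord(tx, b))) cds_hit <- TRUE
    else if (nrow(tx$cds) > 0) {
      cl <- min(tx$cds$start); ch <- max(tx$cds$end)
      five <- if (tx$strand == "+") b < cl else b > ch
      terms <- c(terms, if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant")
    }
  }
  is_indel <- rlen != alen
  if (cds_hit && !(is_indel && intronic_hit)) {
    if (rlen == 1 && alen == 1) {
      terms <- c(terms, snv_cds_term(tx, genome, pos, alt))
    } else if (is_indel) {
      net <- alen - rlen
      terms <- c(terms,
                 if (net %% 3 != 0) "frameshift_variant"
                 else if (net < 0) "inframe_deletion" else "inframe_insertion")
    } else {
      # equal-length multi-base substitution: treated as missense
      terms <- c(terms, "missense_variant")
    }
  }
  unique(terms)
}

snv_cds_term <- function(tx, genome, pos, alt) {
  cpos <- cds_coord(tx, pos)
  cds_seq <- cds_sequence(tx, genome)
  codon_idx <- (cpos - 1) %/% 3 + 1
  within <- (cpos - 1) %% 3 + 1
  codon_start <- (codon_idx - 1) * 3 + 1
  ref_codon <- substr(cds_seq, codon_start, codon_start + 2)
  alt_base <- if (tx$strand == "-") REVCOMP[[alt]] else alt
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
  if (codon_idx == 1) return("start_lost")
  if (!is.na(ref_aa) && ref_aa == "*") {
    if (!is.na(alt_aa) && alt_aa == "*") return("synonymous_variant")
    return("stop_lost")
  }
  if (!is.na(alt_aa) && alt_aa == "*") return("stop_gained")
  if (identical(ref_aa, alt_aa)) return("synonymous_variant")
  "missense_variant"
}

#' Annotate a variant table with consequence bitmasks
#'
#' Runs [assign_consequences()] for every variant against every transcript on
#' the same chromosome and returns one row per interacting pair.
#'
#' @param variants data.table/data.frame with columns chrom (code or name),
#'   pos, ref, alt and optionally id (RSVR id; computed if absent).
#' @param transcripts list of [transcript_model()] objects.
#' @param genome named character vector of chromosome sequences.
#' @return data.table with columns rsvr_id, transcript_id, gene_id, csq.
#' @export
seqfx <- function(variants, transcripts, genome) {
  variants <- as.data.table(variants)
  if (!"id" %in% names(variants)) {
    variants$id <- encode_rsvr(variants$chrom, variants$pos,
                               variants$ref, variants$alt)$id
  }
  cn <- chrom_name(chrom_code(variants$chrom))
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    for (tx in transcripts) {
      terms <- assign_consequences(cn[i], variants$pos[i], variants$ref[i],
                                   variants$alt[i], tx, genome)
      if (length(terms) > 0) {
        rows[[length(rows) + 1]] <- data.table(
          rsvr_id = variants$id[i], transcript_id = tx$transcript_id,
          gene_id = tx$gene_id, csq = encode_csq(terms))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.table(rsvr_id = character(0), transcript_id = character(0),
                      gene_id = character(0), csq = numeric(0)))
  }
  rbindlist(rows)
}
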
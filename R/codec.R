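#' @useDynLib rsvr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

#' Chromosome name to integer code
#'
#' Chromosomes 1-22 map to their number; X, Y and MT map to 23, 24 and 25.
#' A leading "chr" prefix is tolerated. Any other name is an error.
#'
#' @param chrom character or integer vector of chromosome names.
#' @return integer vector of codes in 1-25.
#' @export
chrom_code <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "M"] <- "MT"
  code <- match(x, c(as.character(1:25), "X", "Y", "MT"))
  code[code > 25] <- code[code > 25] - 3L  # X, Y, MT -> 23, 24, 25
  if (anyNA(code)) {
    stop("unsupported chromosome name(s) (expected 1-25, X, Y or MT): ",
         paste(unique(x[is.na(code)]), collapse = ", "))
  }
  as.integer(code)
}

#' @rdname chrom_code
#' @param code integer vector of chromosome codes.
#' @export
chrom_name <- function(code) {
  c(as.character(1:22), "X", "Y", "MT")[as.integer(code)]
}

check_alleles <- function(x, what) {
  x <- toupper(as.character(x))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("symbolic or non-ACGT ", what, " allele(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Normalize a variant by trimming shared allele sequence
#'
#' Removes any sequence shared by the reference and alternate alleles from
#' their starts (advancing the position by the trimmed length) and then from
#' their ends. Either allele may become empty (pure insertion or deletion);
#' re-anchoring with a preceding reference base is left to VCF export.
#' Alleles are case-folded to upper case; symbolic alleles are rejected.
#'
#' @param chrom chromosome names or codes (see [chrom_code()]).
#' @param pos 1-based positions.
#' @param ref,alt allele strings over ACGT; must differ after case-folding.
#' @return data.table with columns chrom (integer code), pos, ref, alt.
#' @examples
#' normalize_variant(1, 100, "AT", "AG")   # -> pos 101, T > G
#' normalize_variant(1, 100, "ACC", "AC")  # -> pos 102, C > ""
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- check_alleles(ref, "reference")
  alt <- check_alleles(alt, "alternate")
  if (any(ref == alt)) stop("ref == alt for ", sum(ref == alt), " variant(s)")
  out <- cpp_trim_alleles(chrom_code(chrom), as.integer(pos), ref, alt)
  setDT(out)
  out[]
}

#' Encode normalized variants as 64-bit RSVR identifiers
#'
#' Packs chromosome (5 bits), position (28), reference and alternate allele
#' lengths (6 each) and a 2-bit-per-base code of the alternate allele (18)
#' into one 63-bit integer, returned as a decimal string. Identifiers are
#' numerically ordered by genomic position. Alternate alleles of ten or more
#' bases are represented by their first five plus last four bases and length
#' fields saturate at 63; either condition marks the encoding `ambiguous`
#' and callers should persist the full alleles separately.
#'
#' @param chrom,pos,ref,alt parallel vectors describing normalized variants
#'   (as produced by [normalize_variant()]).
#' @return data.table with columns id (character decimal) and ambiguous.
#' @examples
#' encode_rsvr(1, 1, "A", "C")$id  # "288230377242492929"
#' @export
encode_rsvr <- function(chrom, pos, ref, alt) {
  out <- cpp_encode_rsvr(chrom_code(chrom), as.integer(pos),
                         toupper(as.character(ref)), toupper(as.character(alt)))
  setDT(out)
  out[]
}

#' Decode RSVR identifiers
#'
#' Unpacks chromosome code, position, allele lengths and the alternate allele
#' bases. The reference sequence is not stored and is never reconstructed.
#' For alternate alleles of ten or more bases only the first five plus last
#' four bases are recovered and `partial` is set.
#'
#' @param id character vector of decimal RSVR ids (MSB unset).
#' @return data.table with columns chrom, pos, ref_len, alt_len, alt, partial.
#' @export
decode_rsvr <- function(id) {
  out <- cpp_decode_rsvr(as.character(id))
  setDT(out)
  out[]
}

#' Encode and decode simple structural variants
#'
#' Structural variants expressible as a start and a length share the 64-bit id
#' space with small variants by setting the most significant bit, followed by
#' the type (2 bits: deletion 0, duplication 1, inversion 2, insertion 3), the
#' chromosome (5 bits) and the start and length (28 bits each).
#'
#' @param sv_type integer 0-3.
#' @param chrom chromosome names or codes.
#' @param start,length non-negative integers below 2^28.
#' @return character vector of decimal ids (`encode_sv`); data.table with
#'   columns sv_type, chrom, start, length (`decode_sv`).
#' @export
encode_sv <- function(sv_type, chrom, start, length) {
  cpp_encode_sv(as.integer(sv_type), chrom_code(chrom),
                as.integer(start), as.integer(length))
}

#' @rdname encode_sv
#' @param id character vector of decimal structural-variant ids (MSB set).
#' @export
decode_sv <- function(id) {
  out <- cpp_decode_sv(as.character(id))
  setDT(out)
  out[]
}

#' Order and compare 64-bit ids numerically
#'
#' Decimal id strings are compared by their unsigned 64-bit value, so small
#' variants sort by genomic position and all structural-variant ids sort after
#' all small-variant ids.
#'
#' @param id,a,b character vectors of decimal ids.
#' @return `rsvr_order`: an order permutation; `rsvr_lt`: logical; `is_sv_id`:
#'   logical, TRUE for structural-variant ids.
#' @export
rsvr_order <- function(id) cpp_u64_order(as.character(id))

#' @rdname rsvr_order
#' @export
rsvr_lt <- function(a, b) cpp_u64_lt(as.character(a), as.character(b))

#' @rdname rsvr_order
#' @export
is_sv_id <- function(id) cpp_is_sv_id(as.character(id))

# Single source of truth for the consequence severity order (least to most
# severe). Bit i-1 of the consequence bitmask holds term i of this list, so
# larger masks (after isolating the highest set bit) mean more severe impact.
SO_SEVERITY <- c(
  "intergenic_variant",
  "downstream_gene_variant",
  "upstream_gene_variant",
  "intron_variant",
  "3_prime_UTR_variant",
  "5_prime_UTR_variant",
  "synonymous_variant",
  "splice_region_variant",
  "inframe_insertion",
  "inframe_deletion",
  "missense_variant",
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_gained",
  "frameshift_variant",
  "stop_lost",
  "start_lost"
)

CSQ_HIGH <- c("start_lost", "stop_lost", "frameshift_variant", "stop_gained",
              "splice_donor_variant", "splice_acceptor_variant")
CSQ_MODERATE_EXTRA <- c("missense_variant", "inframe_deletion")

#' Consequence severity table
#'
#' The registered Sequence Ontology terms in increasing order of severity.
#' The position of a term (1-based) minus one is its bit index in the
#' consequence bitmask.
#'
#' @return character vector of SO term names.
#' @export
csq_severity_table <- function() SO_SEVERITY

csq_bit <- function(terms) {
  i <- match(terms, SO_SEVERITY)
  if (anyNA(i)) {
    stop("unknown consequence term(s): ",
         paste(unique(terms[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

#' Consequence bitmasks
#'
#' `encode_csq` folds a set of SO terms into an integer bitmask with one bit
#' per registered term, more severe terms occupying higher bits (so masks can
#' be thresholded or sorted by severity). `decode_csq` inverts it,
#' `worst_consequence` names the highest set bit (NA for an empty mask) and
#' `meets_impact` tests membership of the three analysis classes: "high"
#' (start/stop loss or gain, frameshift, splice donor/acceptor), "moderate"
#' (high plus missense and in-frame deletion; high-impact variants are capable
#' of loss of function and are embedded in the moderate class) and "utr5"
#' (5' UTR).
#'
#' @param terms character vector of SO terms (one variant's set).
#' @param mask numeric bitmask(s) from `encode_csq`.
#' @param class one of "high", "moderate", "utr5".
#' @return `encode_csq`: a double scalar mask; `decode_csq`: character vector
#'   of terms; `worst_consequence`: character; `meets_impact`: logical.
#' @examples
#' m <- encode_csq(c("missense_variant", "synonymous_variant"))
#' worst_consequence(m)       # "missense_variant"
#' meets_impact(m, "moderate")  # TRUE
#' @export
encode_csq <- function(terms) {
  if (length(terms) == 0) return(0)
  sum(2^unique(csq_bit(terms)))
}

#' @rdname encode_csq
#' @export
decode_csq <- function(mask) {
  stopifnot(length(mask) == 1, mask >= 0)
  SO_SEVERITY[floor(mask / 2^(seq_along(SO_SEVERITY) - 1)) %% 2 == 1]
}

#' @rdname encode_csq
#' @export
worst_consequence <- function(mask) {
  vapply(mask, function(m) {
    t <- decode_csq(m)
    if (length(t) == 0) NA_character_ else t[length(t)]
  }, character(1))
}

#' @rdname encode_csq
#' @export
meets_impact <- function(mask, class = c("high", "moderate", "utr5")) {
  class <- match.arg(class)
  sel <- switch(class,
                high = CSQ_HIGH,
                moderate = c(CSQ_HIGH, CSQ_MODERATE_EXTRA),
                utr5 = "5_prime_UTR_variant")
  bits <- csq_bit(sel)
  vapply(mask, function(m) any(floor(m / 2^bits) %% 2 == 1), logical(1))
}
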
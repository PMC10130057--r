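# Metatranscriptomic quantification: alignment filtering, TPM, and the
# CDS -> gene complex -> reaction -> pathway aggregation hierarchy.

#' Filter alignment records on aligned fraction and identity
#'
#' Two filtering dialects are supported, matching the differing strictness
#' used for metagenomic and metatranscriptomic read mapping:
#' \itemize{
#'   \item `strict = TRUE` (metagenomic): remove alignments with aligned
#'     length <= `min_aligned_frac` of read length OR identity
#'     <= `min_identity` (equality removed); defaults 0.90 / 0.97.
#'   \item `strict = FALSE` (metatranscriptomic): remove on strict
#'     inequality only (< thresholds; equality survives); defaults
#'     0.95 / 0.97.
#' }
#'
#' @param records data frame with columns `read_id`, `target_id`,
#'   `read_length`, `aligned_length`, `identity`.
#' @param min_aligned_frac aligned-length threshold as a fraction of read
#'   length, in (0, 1].
#' @param min_identity identity threshold, in (0, 1].
#' @param strict logical; filtering dialect (see above).
#' @return the surviving records, input order preserved.
#' @export
filter_alignments <- function(records,
                              min_aligned_frac = if (strict) 0.90 else 0.95,
                              min_identity = 0.97,
                              strict = FALSE) {
  check_columns(records,
                c("read_id", "target_id", "read_length", "aligned_length",
                  "identity"), "alignment table")
  if (min_aligned_frac <= 0 || min_aligned_frac > 1 ||
      min_identity <= 0 || min_identity > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (nrow(records) == 0) return(records)
  if (any(records$aligned_length > records$read_length)) {
    stop("aligned_length exceeds read_length", call. = FALSE)
  }
  if (any(records$identity < 0 | records$identity > 1)) {
    stop("identity must lie in [0, 1]", call. = FALSE)
  }
  frac <- records$aligned_length / records$read_length
  drop <- if (strict) {
    frac <= min_aligned_frac | records$identity <= min_identity
  } else {
    frac < min_aligned_frac | records$identity < min_identity
  }
  records[!drop, , drop = FALSE]
}

#' Count reads per CDS from surviving alignments
#'
#' Each read is assigned to the CDS of its best surviving alignment (highest
#' identity, then longest alignment); remaining ties go to the first-listed
#' target and are tallied in the `ties` attribute.
#'
#' @param records filtered alignment records (see [filter_alignments()]).
#' @param cds_ids character vector of all CDS ids (zero counts included).
#' @return named integer vector of counts per CDS, with attribute `ties`.
#' @export
count_reads <- function(records, cds_ids) {
  counts <- stats::setNames(integer(length(cds_ids)), cds_ids)
  ties <- 0L
  if (nrow(records) > 0) {
    for (rid in unique(records$read_id)) {
      sub <- records[records$read_id == rid, , drop = FALSE]
      best <- sub[order(-sub$identity, -sub$aligned_length), , drop = FALSE]
      top <- best[best$identity == best$identity[1] &
                    best$aligned_length == best$aligned_length[1], ,
                  drop = FALSE]
      if (nrow(top) > 1) ties <- ties + 1L
      tgt <- top$target_id[1]
      if (tgt %in% cds_ids) counts[[tgt]] <- counts[[tgt]] + 1L
    }
  }
  attr(counts, "ties") <- ties
  counts
}

#' Transcripts per million (TPM)
#'
#' `TPM_i = (c_i / L_i) / sum_j (c_j / L_j) * 1e6`: length-normalised read
#' rates rescaled so all features sum to one million.  All-zero counts give
#' all-zero TPM.
#'
#' @param counts numeric vector of read counts per CDS, >= 0.
#' @param lengths numeric vector of CDS lengths in bp, > 0.
#' @return numeric TPM vector (names taken from `counts`).
#' @examples
#' compute_tpm(c(a = 10, b = 20), c(100, 400))
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths differ in length", call. = FALSE)
  }
  if (any(lengths <= 0)) {
    stop("CDS lengths must be > 0 (offending index ",
         which(lengths <= 0)[1], ")", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  rate <- counts / lengths
  total <- sum(rate)
  tpm <- if (total == 0) rep(0, length(counts)) else rate / total * 1e6
  stats::setNames(tpm, names(counts))
}

#' Define the gene-complex / reaction / pathway aggregation hierarchy
#'
#' @param complexes named list: complex id -> character vector of member
#'   gene symbols (subunits).
#' @param reactions named list: reaction id -> character vector of
#'   alternate complex ids catalysing it.
#' @param pathways named list: pathway id -> character vector of reaction
#'   ids.
#' @return object of class `"function_map"`.
#' @examples
#' function_map(
#'   complexes = list(nar = c("narG", "narH"), nap = c("napA", "napB")),
#'   reactions = list(nitrate_reduction = c("nar", "nap")),
#'   pathways = list(denitrification = "nitrate_reduction"))
#' @export
function_map <- function(complexes = list(), reactions = list(),
                         pathways = list()) {
  check_sets <- function(x, what) {
    if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop(what, " must be a named list", call. = FALSE)
    }
    empty <- vapply(x, length, 0L) == 0
    if (any(empty)) {
      stop("empty member set in ", what, ": ",
           paste(names(x)[empty], collapse = ", "), call. = FALSE)
    }
  }
  check_sets(complexes, "complexes")
  check_sets(reactions, "reactions")
  check_sets(pathways, "pathways")
  undef_cx <- setdiff(unlist(reactions), names(complexes))
  if (length(undef_cx) > 0) {
    stop("reaction references undefined complex(es): ",
         paste(undef_cx, collapse = ", "), call. = FALSE)
  }
  undef_rx <- setdiff(unlist(pathways), names(reactions))
  if (length(undef_rx) > 0) {
    stop("pathway references undefined reaction(s): ",
         paste(undef_rx, collapse = ", "), call. = FALSE)
  }
  structure(list(complexes = complexes, reactions = reactions,
                 pathways = pathways), class = "function_map")
}

# Sum TPM per gene symbol within one genome (copies of a gene are additive).
gene_tpm <- function(tpm, cds, genome) {
  idx <- cds$genome_id == genome
  tapply(tpm[cds$cds_id[idx]], cds$gene_symbol[idx], sum)
}

#' Expression of a multi-subunit gene complex
#'
#' The expression of an enzyme complex is the arithmetic mean of the TPM of
#' the genes encoding its subunits (e.g. a three-subunit methane
#' monooxygenase is the mean of the C, A and B subunit TPMs).  Multiple CDS
#' copies of one subunit within the genome are summed before averaging.
#' Subunits with no CDS in the genome contribute 0 and set the
#' `missing_members` flag; a complex with no resolvable member at all is
#' returned as `NA` with flag `"not encoded"`.
#'
#' @param tpm named numeric vector of per-CDS TPM.
#' @param cds CDS annotation data frame with columns `cds_id`, `genome_id`,
#'   `gene_symbol`.
#' @param function_map a [function_map()].
#' @param genome genome id whose complexes are evaluated.
#' @return data frame with columns `complex_id`, `value`, `flag`.
#' @examples
#' cds <- data.frame(cds_id = c("c1", "c2", "c3"), genome_id = "G1",
#'                   gene_symbol = c("pmoC", "pmoA", "pmoB"))
#' fm <- function_map(complexes = list(pmoCAB = c("pmoC", "pmoA", "pmoB")))
#' complex_expression(c(c1 = 30, c2 = 60, c3 = 90), cds, fm, "G1")
#' @export
complex_expression <- function(tpm, cds, function_map, genome) {
  stopifnot(inherits(function_map, "function_map"))
  check_columns(cds, c("cds_id", "genome_id", "gene_symbol"), "CDS table")
  gt <- gene_tpm(tpm, cds, genome)
  out <- lapply(names(function_map$complexes), function(cx) {
    members <- function_map$complexes[[cx]]
    present <- members %in% names(gt)
    if (!any(present)) {
      return(data.frame(complex_id = cx, value = NA_real_,
                        flag = "not encoded"))
    }
    vals <- ifelse(present, unname(gt[members]), 0)
    data.frame(complex_id = cx, value = mean(vals),
               flag = if (all(present)) "" else "missing_members")
  })
  do.call(rbind, out)
}

#' Expression of a reaction from its alternate complexes
#'
#' Reactions catalysed by multiple alternate enzymes are scored as the sum
#' of the alternates' complex expressions (e.g. nitrate reduction = nar +
#' nap).  Complexes flagged "not encoded" contribute 0.
#'
#' @param complex_values data frame from [complex_expression()].
#' @param function_map a [function_map()].
#' @return data frame with columns `reaction_id`, `value`, `flag`.
#' @export
reaction_expression <- function(complex_values, function_map) {
  stopifnot(inherits(function_map, "function_map"))
  out <- lapply(names(function_map$reactions), function(rx) {
    alts <- function_map$reactions[[rx]]
    rows <- complex_values[complex_values$complex_id %in% alts, ,
                           drop = FALSE]
    vals <- rows$value[!is.na(rows$value)]
    encoded <- length(vals) > 0
    data.frame(reaction_id = rx,
               value = if (encoded) sum(vals) else 0,
               flag = if (encoded) "" else "not encoded")
  })
  do.call(rbind, out)
}

#' Expression of a pathway from its reactions
#'
#' Pathway expression is the arithmetic mean of the expression of its
#' reactions; reactions absent from the input count as 0 and flag the
#' pathway.  A pathway with no encoded reaction is 0, flagged "not encoded".
#'
#' @param reaction_values data frame from [reaction_expression()].
#' @param function_map a [function_map()].
#' @return data frame with columns `pathway_id`, `value`, `flag`.
#' @export
pathway_expression <- function(reaction_values, function_map) {
  stopifnot(inherits(function_map, "function_map"))
  out <- lapply(names(function_map$pathways), function(pw) {
    rxns <- function_map$pathways[[pw]]
    vals <- vapply(rxns, function(rx) {
      row <- reaction_values[reaction_values$reaction_id == rx, ,
                             drop = FALSE]
      if (nrow(row) == 0) NA_real_ else row$value[1]
    }, numeric(1))
    flagged <- reaction_values$reaction_id[
      reaction_values$flag == "not encoded"]
    absent <- is.na(vals) | rxns %in% flagged
    data.frame(
      pathway_id = pw,
      value = mean(ifelse(is.na(vals), 0, vals)),
      flag = if (all(absent)) "not encoded"
             else if (any(absent)) "missing_reactions" else "")
  })
  do.call(rbind, out)
}

#' Contribution of each genome to the metatranscriptome
#'
#' The relative contribution of a genome (MAG) is the sum of TPM over all of
#' its CDS, expressed as a percentage of the one-million TPM total; CDS on
#' unbinned scaffolds report under `"unbinned"`.  Fractions sum to 100 when
#' any read was counted.
#'
#' @param tpm named numeric per-CDS TPM.
#' @param cds CDS table with columns `cds_id`, `genome_id`.
#' @return named numeric vector, percent per genome (including
#'   `"unbinned"` when present).
#' @export
mag_expression_fraction <- function(tpm, cds) {
  check_columns(cds, c("cds_id", "genome_id"), "CDS table")
  per <- tapply(tpm[cds$cds_id], cds$genome_id, sum)
  out <- as.numeric(per) / 1e6 * 100
  stats::setNames(out, names(per))
}

#' Relative abundance of genomes from mapped read counts
#'
#' Abundance of each genome is its mapped reads divided by the sample's
#' total quality-trimmed reads, in percent; the unassigned remainder (reads
#' mapping nowhere or to unbinned scaffolds) is reported as
#' `"unmapped_or_unbinned"`.
#'
#' @param mapped_reads named numeric vector of mapped read counts per
#'   genome.
#' @param total_reads total trimmed reads of the sample, > 0.
#' @return named numeric vector of percentages, including the remainder.
#' @export
mag_relative_abundance <- function(mapped_reads, total_reads) {
  stopifnot(total_reads > 0, all(mapped_reads >= 0))
  if (sum(mapped_reads) > total_reads) {
    stop("mapped reads exceed total reads", call. = FALSE)
  }
  pct <- mapped_reads / total_reads * 100
  c(pct, unmapped_or_unbinned = 100 - sum(pct))
}

#' Relativize CDS expression to the genome median
#'
#' Expression heatmaps are commonly scaled per genome: each CDS TPM is
#' divided by the median TPM over all CDS of that genome and (by default)
#' log2-transformed, so a value of one means twice the genome-median
#' expression.  CDS with zero TPM are flagged `"undetectable"` rather than
#' mapped to minus infinity; if the genome median itself is zero every CDS
#' is flagged.
#'
#' @param tpm named numeric per-CDS TPM.
#' @param cds CDS table with columns `cds_id`, `genome_id`.
#' @param mode `"log2"` (default; `log2(TPM / median)`) or `"ratio"`
#'   (plain `TPM / median`).
#' @return data frame with columns `cds_id`, `genome_id`, `value`, `flag`.
#' @export
relativize_to_median <- function(tpm, cds, mode = c("log2", "ratio")) {
  mode <- match.arg(mode)
  check_columns(cds, c("cds_id", "genome_id"), "CDS table")
  out <- lapply(unique(cds$genome_id), function(g) {
    ids <- cds$cds_id[cds$genome_id == g]
    vals <- tpm[ids]
    med <- stats::median(vals)
    undetect <- vals == 0 | med == 0
    rel <- rep(NA_real_, length(ids))
    if (med > 0) {
      ratio <- vals[!undetect] / med
      rel[!undetect] <- if (mode == "log2") log2(ratio) else ratio
    }
    data.frame(cds_id = ids, genome_id = g, value = rel,
               flag = ifelse(undetect, "undetectable", ""),
               row.names = NULL)
  })
  do.call(rbind, out)
}
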
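# File formats: tidy measurement series, count tables, function maps,
# abundance profiles, CDS annotations (TSV or GFF3).
#
# Every writer prepends '#'-comment header lines carrying the package
# version, the seed (when given) and a short config hash, so outputs are
# self-describing; every reader skips comment lines.

# 32-bit polynomial string hash for the reproducibility header (kept in
# double arithmetic: exact below 2^53).
config_hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

output_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("guildflux"))
  h <- config_hash32(paste(deparse(config), collapse = ""))
  paste0("# guildflux ", ver,
         if (!is.null(seed)) paste0(" | seed=", seed) else "",
         " | config_hash=", h)
}

write_tsv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  # write.table warns about "appending column names" on an open connection
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

read_tsv_skip_comments <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, required, what)
  df
}

#' Write / read a tidy measurement series
#'
#' Schema: tab-separated columns `time_d`, `species`, `value`, `unit`;
#' lines starting with `#` are reproducibility headers.  Numbers use the
#' locale-independent decimal point.
#'
#' @param series data frame with the schema columns.
#' @param path file path.
#' @param seed,config optional provenance recorded in the header.
#' @return `read_series` returns the data frame; `write_series` the path,
#'   invisibly.
#' @export
write_series <- function(series, path, seed = NULL, config = NULL) {
  check_columns(series, c("time_d", "species", "value", "unit"),
                "measurement series")
  write_tsv_with_header(series, path, seed, config)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read_tsv_skip_comments(path, c("time_d", "species", "value"),
                               "measurement series")
  bad <- which(!is.finite(df$value) | !is.finite(df$time_d))
  if (length(bad) > 0) {
    stop("malformed measurement series row ", bad[1], " in ", path,
         call. = FALSE)
  }
  df
}

#' Write / read a per-CDS count table
#'
#' Schema: columns `cds_id`, `genome_id`, `gene_symbol`, `length`,
#' `strand`, `count` (plus optional `tpm`).
#'
#' @param cds CDS annotation data frame.
#' @param counts named numeric vector of counts per `cds_id`.
#' @param path file path.
#' @param tpm optional named numeric TPM vector to include.
#' @param seed,config optional provenance for the header.
#' @return `read_counts` returns a list with `cds` (data frame) and
#'   `counts` (named vector), plus `tpm` when present.
#' @export
write_counts <- function(cds, counts, path, tpm = NULL, seed = NULL,
                         config = NULL) {
  check_columns(cds, c("cds_id", "genome_id", "length"), "CDS table")
  df <- cds
  df$count <- as.numeric(counts[df$cds_id])
  if (!is.null(tpm)) df$tpm <- as.numeric(tpm[df$cds_id])
  write_tsv_with_header(df, path, seed, config)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv_skip_comments(path, c("cds_id", "genome_id", "length",
                                       "count"), "count table")
  bad <- which(df$length <= 0)
  if (length(bad) > 0) {
    stop("non-positive CDS length at row ", bad[1], " (", df$cds_id[bad[1]],
         ") in ", path, call. = FALSE)
  }
  bad <- which(df$count < 0)
  if (length(bad) > 0) {
    stop("negative count at row ", bad[1], " in ", path, call. = FALSE)
  }
  out <- list(cds = df[setdiff(names(df), c("count", "tpm"))],
              counts = stats::setNames(df$count, df$cds_id))
  if ("tpm" %in% names(df)) out$tpm <- stats::setNames(df$tpm, df$cds_id)
  out
}

#' Read a function map from a structured YAML config
#'
#' Expected top-level keys: `complexes` (complex -> member gene symbols),
#' `reactions` (reaction -> alternate complexes), `pathways`
#' (pathway -> reactions).
#'
#' @param path YAML file path.
#' @return a [function_map()].
#' @export
read_function_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("complexes", "reactions", "pathways"))
  if (length(unknown) > 0) {
    stop("unknown key(s) in function map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as_sets <- function(x) lapply(x, function(v) as.character(unlist(v)))
  function_map(
    complexes = as_sets(cfg$complexes %||% list()),
    reactions = as_sets(cfg$reactions %||% list()),
    pathways = as_sets(cfg$pathways %||% list())
  )
}

#' Read abundance profiles from a sample-by-category matrix
#'
#' Schema: first column `sample`, remaining columns one per category,
#' nonnegative counts or proportions.
#'
#' @param path TSV file path.
#' @return named list of [abundance_profile()]s, one per sample row.
#' @export
read_profiles <- function(path) {
  df <- read_tsv_skip_comments(path, "sample", "profile matrix")
  cats <- setdiff(names(df), "sample")
  if (length(cats) == 0) stop("profile matrix has no categories",
                              call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    abundance_profile(stats::setNames(as.numeric(df[i, cats]), cats))
  })
  names(out) <- df$sample
  out
}

#' @rdname read_profiles
#' @param profiles named list of profiles (or numeric vectors).
#' @param seed,config optional provenance for the header.
#' @export
write_profiles <- function(profiles, path, seed = NULL, config = NULL) {
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "abundance_profile")) {
      stats::setNames(p$p, p$labels)
    } else p
  })
  df <- cbind(data.frame(sample = names(rows) %||%
                           paste0("S", seq_along(rows))),
              do.call(rbind, rows))
  write_tsv_with_header(df, path, seed, config)
}

#' Read CDS annotations from GFF3
#'
#' CDS features are read from a GFF3 file (1-based inclusive coordinates;
#' length = end - start + 1).  Attributes `gene_symbol` (fallback: `gene`,
#' `Name`), `genome_id` and `complex_id` are honoured when present.
#'
#' @param path GFF3 file path.
#' @return CDS annotation data frame (`cds_id`, `genome_id`,
#'   `gene_symbol`, `length`, `strand`).
#' @export
read_cds_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_cds_gff3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", path, call. = FALSE)
  meta <- S4Vectors::mcols(gr)
  pick <- function(keys, default) {
    for (k in keys) if (k %in% names(meta)) return(as.character(meta[[k]]))
    rep(default, length(gr))
  }
  data.frame(
    cds_id = pick(c("ID", "Name"), NA_character_),
    genome_id = pick("genome_id", "unbinned"),
    gene_symbol = pick(c("gene_symbol", "gene", "Name"), NA_character_),
    length = BiocGenerics::width(gr),  # end - start + 1 under GFF3 1-based
    strand = as.character(BiocGenerics::strand(gr))
  )
}
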
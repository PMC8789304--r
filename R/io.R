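# Readers and writers for the on-disk formats: BED locus tables, FASTA
# sequences, rpm TSVs, the truth record (JSON), and provenance headers.
#
# All tabular files are UTF-8 TSV with '#'-prefixed header lines; loci use
# 6 standard BED columns (contig, start, end, name, score, strand) plus 4
# extension columns (family, paralog_label, subgenome, node_of_origin).
# Coordinates are 0-based half-open throughout.

BED_COLUMNS <- c("contig", "start", "end", "locus_id", "score", "strand",
                 "family", "paralog_label", "subgenome", "node_of_origin")

provenance_header <- function(seed = NULL, extra = NULL) {
  ver <- as.character(utils::packageVersion("wgdmirna"))
  h <- sprintf("# wgdmirna %s", ver)
  if (!is.null(seed)) h <- paste0(h, sprintf("; seed=%d", as.integer(seed)))
  if (!is.null(extra)) h <- paste0(h, "; ", extra)
  h
}

#' Write a locus table as extended BED
#'
#' @param loci locus table.
#' @param path output file.
#' @param seed optional RNG seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path, seed = NULL) {
  validate_loci(loci)
  out <- data.frame(contig = loci$contig, start = loci$start, end = loci$end,
                    locus_id = loci$locus_id, score = 0L,
                    strand = loci$strand, family = loci$family,
                    paralog_label = ifelse(nzchar(loci$paralog_label),
                                           loci$paralog_label, "."),
                    subgenome = loci$subgenome,
                    node_of_origin = loci$node_of_origin,
                    stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  writeLines(paste0("# ", paste(BED_COLUMNS, collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an extended-BED locus table
#'
#' Expects the 6 standard BED columns plus the 4 extension columns
#' (family, paralog_label, subgenome, node_of_origin). `#` lines are
#' ignored; CRLF and LF files parse identically. Malformed lines are
#' reported with their line numbers.
#'
#' @param path file to read.
#' @return a locus table.
#' @export
read_loci_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(keep)) {
    loci <- data.frame(locus_id = character(0), family = character(0),
                       paralog_label = character(0), contig = character(0),
                       lg = character(0), start = integer(0), end = integer(0),
                       strand = character(0), subgenome = character(0),
                       node_of_origin = character(0), stringsAsFactors = FALSE)
    return(loci)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(BED_COLUMNS))) {
    bad <- keep[nf != length(BED_COLUMNS)][1L]
    stop(sprintf("line %d of %s: expected %d tab-separated fields, found %d",
                 bad, path, length(BED_COLUMNS), nf[match(bad, keep)]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- keep[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("line %d of %s: non-numeric coordinates", bad, path))
  }
  if (any(start < 0 | end <= start)) {
    bad <- keep[which(start < 0 | end <= start)[1L]]
    stop(sprintf(
      "line %d of %s: invalid interval (0-based half-open requires 0 <= start < end)",
      bad, path))
  }
  loci <- data.frame(
    locus_id = m[, 4L], family = m[, 7L],
    paralog_label = ifelse(m[, 8L] == ".", "", m[, 8L]),
    contig = m[, 1L],
    lg = mapply(function(ct, sg) {
      if (sg == "none") ct else sub(paste0("_", sg, "$"), "", ct)
    }, m[, 1L], m[, 9L], USE.NAMES = FALSE),
    start = start, end = end, strand = m[, 6L], subgenome = m[, 9L],
    node_of_origin = m[, 10L], stringsAsFactors = FALSE
  )
  validate_loci(loci)
}

#' Write precursor sequences as FASTA
#' @param loci locus table with `pre_seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pre_fasta <- function(loci, path) {
  validate_loci(loci, require_seqs = TRUE)
  ss <- Biostrings::DNAStringSet(stats::setNames(loci$pre_seq, loci$locus_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write mature-arm sequences as FASTA
#'
#' Records both arms per locus as `<locus_id>|5p` and `<locus_id>|3p`.
#' @inheritParams write_pre_fasta
#' @export
write_mature_fasta <- function(loci, path) {
  validate_loci(loci, require_seqs = TRUE)
  seqs <- c(stats::setNames(loci$mature5p, paste0(loci$locus_id, "|5p")),
            stats::setNames(loci$mature3p, paste0(loci$locus_id, "|3p")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Attach sequences from FASTA files to a locus table
#'
#' @param loci locus table (e.g. from [read_loci_bed()]).
#' @param pre_fasta precursor FASTA (names = locus ids).
#' @param mature_fasta mature FASTA (names = `<locus_id>|5p` / `|3p`).
#' @return the locus table with `pre_seq`, `mature5p`, `mature3p` columns.
#' @export
attach_sequences <- function(loci, pre_fasta, mature_fasta) {
  validate_loci(loci)
  pre <- Biostrings::readDNAStringSet(pre_fasta)
  mat <- Biostrings::readDNAStringSet(mature_fasta)
  loci$pre_seq <- as.character(pre)[loci$locus_id]
  loci$mature5p <- as.character(mat)[paste0(loci$locus_id, "|5p")]
  loci$mature3p <- as.character(mat)[paste0(loci$locus_id, "|3p")]
  if (anyNA(loci$pre_seq) || anyNA(loci$mature5p)) {
    stop("FASTA files do not cover every locus id")
  }
  validate_loci(loci, require_seqs = TRUE)
}

#' Write an expression table
#' @param expr `data.frame(locus_id, rpm)`.
#' @param path output file.
#' @param seed optional seed recorded in the header.
#' @export
write_rpm_tsv <- function(expr, path, seed = NULL) {
  stopifnot(all(c("locus_id", "rpm") %in% names(expr)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  writeLines("# locus_id\trpm", con)
  utils::write.table(expr[, c("locus_id", "rpm")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table
#' @param path file written by [write_rpm_tsv()].
#' @return `data.frame(locus_id, rpm)`.
#' @export
read_rpm_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    return(data.frame(locus_id = character(0), rpm = numeric(0)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  data.frame(locus_id = vapply(fields, `[`, "", 1L),
             rpm = as.numeric(vapply(fields, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

# truth record <-> JSON (snapshots are stored without sequence columns)
truth_for_json <- function(truth) {
  slim <- lapply(truth$snapshots, function(g) {
    g[, intersect(c("locus_id", "family", "subgenome", "node_of_origin",
                    "contig", "start", "end", "anc_unit"), names(g)),
      drop = FALSE]
  })
  truth$snapshots <- slim
  truth
}

#' Write a simulation truth record as JSON
#' @param truth the `truth` element of a [simulate_clade()] result.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth_for_json(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write all outputs of a clade simulation
#'
#' Emits, per leaf taxon, `<taxon>.loci.bed`, `<taxon>.pre.fasta`,
#' `<taxon>.mature.fasta` and `<taxon>.rpm.tsv`, plus the annotated
#' `tree.nwk` and `truth.json`.
#'
#' @param sim a [simulate_clade()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "wgd_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- sim$truth$rng_seed
  for (tx in names(sim$genomes)) {
    g <- sim$genomes[[tx]]
    write_loci_bed(g, file.path(dir, paste0(tx, ".loci.bed")), seed = seed)
    if ("pre_seq" %in% names(g)) {
      write_pre_fasta(g, file.path(dir, paste0(tx, ".pre.fasta")))
      write_mature_fasta(g, file.path(dir, paste0(tx, ".mature.fasta")))
    }
    write_rpm_tsv(sim$expression[[tx]],
                  file.path(dir, paste0(tx, ".rpm.tsv")), seed = seed)
  }
  write_wgd_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

# Generic TSV report writer with provenance header.
write_report_tsv <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
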
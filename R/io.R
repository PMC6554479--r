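meta_lines <- function(extra = character()) {
  c(sprintf("# centwave %s", as.character(utils::packageVersion("centwave"))),
    if (length(extra)) paste0("# ", names(extra), "=", unname(extra)))
}

#' Write a density profile as BED-like TSV
#'
#' Columns `chrom start end count` (0-based half-open), preceded by
#' `#`-prefixed metadata lines recording the tool version and any options.
#'
#' @param profile A `density_profile`.
#' @param path Output path.
#' @param metadata Named character vector of extra `key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, metadata = character()) {
  stopifnot(inherits(profile, "density_profile"))
  df <- as.data.frame(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(c(kind = profile$kind, metadata)), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a density profile TSV written by [write_profile_tsv()]
#'
#' @param path Input path.
#' @return A `density_profile` (kind recovered from the metadata header,
#'   `"snp"` if absent).
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kind <- sub("^# kind=", "", grep("^# kind=", hdr, value = TRUE))
  if (length(kind) != 1L) kind <- "snp"
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "count") %in% names(df))) {
    stop(sprintf("%s is not a centwave profile TSV", path))
  }
  window_size <- max(df$end - df$start)
  grid <- make_windows(max(df$end), window_size, chrom = df$chrom[1])
  if (n_windows(grid) != nrow(df)) stop(sprintf("%s: windows do not tile", path))
  new_density_profile(grid, kind, df$count)
}

#' Write a wavelet landscape as TSV
#'
#' First column `scale`; remaining columns are window start coordinates;
#' one row per scale (ascending). Metadata headers record the normalization
#' and boundary rule so cross-scale comparisons stay traceable.
#'
#' @param landscape A `wavelet_landscape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  stopifnot(inherits(landscape, "wavelet_landscape"))
  starts <- if (!is.null(landscape$grid)) landscape$grid$starts
            else seq_len(ncol(landscape$coeffs)) - 1
  df <- data.frame(scale = landscape$scales, landscape$coeffs,
                   check.names = FALSE)
  colnames(df) <- c("scale", starts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(c(norm = landscape$norm,
                          boundary = landscape$boundary)), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a wavelet landscape TSV written by [write_landscape_tsv()]
#' @param path Input path.
#' @return A `wavelet_landscape` (no grid attached).
#' @export
read_landscape_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    v <- sub(sprintf("^# %s=", key), "", grep(sprintf("^# %s=", key), hdr, value = TRUE))
    if (length(v) == 1L) v else default
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  structure(list(scales = df$scale,
                 coeffs = as.matrix(df[, -1, drop = FALSE]),
                 norm = get_meta("norm", "l2"),
                 boundary = get_meta("boundary", "reflect"),
                 grid = NULL, kind = NULL),
            class = "wavelet_landscape")
}

#' Read biallelic SNP sites and genotypes from a VCF
#'
#' Parses GT fields into ALT-allele dosages; missing calls (`./.`) become
#' `NA`. Multiallelic rows and non-SNP records are skipped with a message
#' giving the count. VCF 1-based positions are converted to 0-based.
#'
#' @param path VCF path (plain text).
#' @return A `genotype_matrix`.
#' @export
read_vcf_sites <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop(sprintf("%s contains no variant records", path))
  if (!"FORMAT" %in% colnames(v@gt)) stop("VCF has no genotype (GT) data")
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skip))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  parse_gt <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  dosage <- matrix(parse_gt(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt))
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.numeric(fix[keep, "POS"]) - 1,
                      ref = ref[keep], alt = alt[keep])
  genotype_matrix(t(dosage), sites, individuals = colnames(gt))
}

#' Write a genotype matrix as a minimal VCF
#'
#' VCF 4.2 with GT-only FORMAT; dosages 0/1/2 become `0/0`, `0/1`, `1/1`
#' and `NA` becomes `./.`. Positions are converted back to 1-based.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=centwave%s", utils::packageVersion("centwave")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals), collapse = "\t")), con)
  for (s in seq_len(ncol(gm$dosage))) {
    d <- gm$dosage[, s]
    g <- ifelse(is.na(d), "./.", gt_str[d + 1L])
    writeLines(paste(c(gm$sites$chrom[s], format(gm$sites$pos[s] + 1, scientific = FALSE),
                       ".", gm$sites$ref[s], gm$sites$alt[s], ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene bodies from a GFF3 annotation
#'
#' Extracts `type == "gene"` features on one chromosome; GFF3 1-based
#' inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 path.
#' @param chrom Chromosome to extract.
#' @return An `interval_set`.
#' @export
read_gff3_genes <- function(path, chrom) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom &
             as.character(gr$type) == "gene"]
  interval_set(start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr), chrom = chrom)
}

#' Read intervals from a BED file
#'
#' BED coordinates are already 0-based half-open and are used as-is.
#'
#' @param path BED3+ path.
#' @param chrom Optional chromosome filter.
#' @return An `interval_set`.
#' @export
read_bed <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(sprintf("%s: BED needs at least 3 columns", path))
  if (!is.null(chrom)) df <- df[df[[1]] == chrom, , drop = FALSE]
  interval_set(start = df[[2]], end = df[[3]],
               chrom = if (is.null(chrom) && nrow(df)) df[1, 1] else chrom)
}

#' Read subject-side intervals from BLAST tabular (outfmt 6) hits
#'
#' Uses columns 2 (subject id), 9 (sstart) and 10 (send); reverse-strand
#' hits (`sstart > send`) are normalized to forward `[min-1, max)` 0-based
#' half-open intervals.
#'
#' @param path BLAST outfmt-6 TSV path.
#' @param chrom Optional subject-sequence filter.
#' @return An `interval_set`.
#' @export
read_blast6 <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop(sprintf("%s: outfmt 6 needs >= 10 columns", path))
  if (!is.null(chrom)) df <- df[df[[2]] == chrom, , drop = FALSE]
  lo <- pmin(df[[9]], df[[10]]); hi <- pmax(df[[9]], df[[10]])
  interval_set(start = lo - 1, end = hi, chrom = chrom)
}

#' Read one chromosome sequence from a FASTA file
#'
#' @param path FASTA path.
#' @param chrom Sequence name (first whitespace-delimited token of the
#'   header); default the first sequence.
#' @return Character string of the sequence.
#' @export
read_fasta <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  if (is.null(chrom)) chrom <- names(ss)[1]
  if (!chrom %in% names(ss)) {
    stop(sprintf("sequence '%s' not found in %s", chrom, path))
  }
  as.character(ss[[chrom]])
}

#' Write CCC edges as TSV
#' @param edges Edge data frame from [ccc_scan()].
#' @param path Output path.
#' @param metadata Named character vector of extra header lines.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path, metadata = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(pairing = attr(edges, "pairing"), reading = attr(edges, "reading"),
            metadata)
  writeLines(meta_lines(meta[!vapply(meta, is.null, logical(1))]), con)
  writeLines(paste(colnames(edges), collapse = "\t"), con)
  if (nrow(edges)) {
    utils::write.table(edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a CCC edge TSV written by [write_edges_tsv()]
#' @param path Input path.
#' @return Edge data frame.
#' @export
read_edges_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  utils::read.table(text = body, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write centromere calls as TSV
#' @param calls A `centromere_call` or list of them.
#' @param path Output path.
#' @param metadata Named character vector of extra header lines.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, metadata = character()) {
  if (inherits(calls, "centromere_call")) calls <- list(calls)
  df <- do.call(rbind, lapply(calls, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(metadata), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
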
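#' Write a synthetic dataset as plain-text files
#'
#' Emits the whole fixture in standard formats: expression TSV (genes x
#' samples with a header row of sample ids), genotype dosage TSV and a
#' minimal VCF with GT fields, gene annotation as both BED (0-based
#' half-open) and GTF (1-based inclusive), the true edge list TSV, the
#' covariate table, and a JSON manifest recording the generator parameters
#' and seed.
#'
#' @param data a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    dosage = file.path(dir, "genotypes.tsv"),
    vcf = file.path(dir, "genotypes.vcf"),
    bed = file.path(dir, "genes.bed"),
    gtf = file.path(dir, "genes.gtf"),
    truth = file.path(dir, "truth_edges.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    manifest = file.path(dir, "manifest.json"))
  expr <- t(data$expression)  # genes x samples
  write.table(data.frame(gene_id = rownames(expr), expr,
                         check.names = FALSE),
              paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(variant_id = colnames(data$genotypes),
                         t(data$genotypes), check.names = FALSE),
              paths["dosage"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_simple_vcf(data$genotypes, data$variant_annotation, paths["vcf"])
  ga <- data$gene_annotation
  write.table(data.frame(ga$chrom, ga$start - 1L, ga$end, ga$gene_id),
              paths["bed"], sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gtf <- data.frame(ga$chrom, "synthetic", "gene", ga$start, ga$end, ".",
                    "+", ".", sprintf('gene_id "%s";', ga$gene_id))
  write.table(gtf, paths["gtf"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(tidy(data$truth)), paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(data$covariates), paths["covariates"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = data$seed, n = nrow(data$expression),
         p = ncol(data$expression), q = ncol(data$genotypes),
         noise_sd = data$truth$noise_sd,
         spectral_bound = data$truth$spectral_bound),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

write_simple_vcf <- function(genotypes, variant_annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(genotypes) %||%
                         paste0("s", seq_len(nrow(genotypes)))),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(variant_annotation$chrom[j],
                       variant_annotation$pos[j],
                       variant_annotation$variant_id[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an expression TSV (genes x samples or samples x genes)
#'
#' Orientation is auto-detected from the header: when the first column is a
#' gene-id column the table is transposed to the internal samples x genes
#' layout.
#'
#' @param path TSV path; first column = gene ids (genes x samples layout)
#'   or sample ids (samples x genes).
#' @param genes_in_rows force the orientation instead of auto-detecting.
#' @return Numeric matrix, samples x genes.
#' @export
read_expression_tsv <- function(path, genes_in_rows = NA) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (is.na(genes_in_rows)) {
    genes_in_rows <- tolower(names(df)[1]) %in%
      c("gene", "gene_id", "geneid", "id")
  }
  if (genes_in_rows) {
    rownames(m) <- ids
    t(m)
  } else {
    rownames(m) <- ids
    m
  }
}

#' Read a genotype dosage TSV (variants x samples)
#'
#' @param path TSV with a `variant_id` first column, one column per sample.
#' @param missing_code value treated as missing (in addition to `NA`).
#' @return Dosage matrix, samples x variants.
#' @export
read_dosage_tsv <- function(path, missing_code = -1) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  m[m == missing_code] <- NA
  m
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Parses GT fields (counting ALT alleles; `./.` becomes `NA`). Only
#' bi-allelic records are supported.
#'
#' @param path VCF path (uncompressed).
#' @return List with `genotypes` (samples x variants dosage matrix) and
#'   `variant_annotation` tibble.
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  rec <- strsplit(body[-1], "\t")
  samples <- hdr[-(1:9)]
  dos <- vapply(rec, function(r) {
    gt <- sub(":.*", "", r[-(1:9)])
    vapply(gt, function(g) {
      if (grepl("\\.", g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]))
    }, numeric(1))
  }, numeric(length(samples)))
  dos <- matrix(dos, nrow = length(samples))
  rownames(dos) <- samples
  colnames(dos) <- vapply(rec, `[[`, character(1), 3)
  ann <- tibble::tibble(
    variant_id = colnames(dos),
    chrom = vapply(rec, `[[`, character(1), 1),
    pos = as.integer(vapply(rec, `[[`, character(1), 2)))
  list(genotypes = dos, variant_annotation = ann)
}

#' Read gene annotation from BED or GTF
#'
#' BED intervals (0-based half-open) are normalized to the internal 1-based
#' inclusive convention; GTF `gene` records are used as-is.
#'
#' @param path file ending in `.bed` or `.gtf`.
#' @return Tibble (gene_id, chrom, start, end), 1-based inclusive.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    tibble::tibble(gene_id = df[[4]], chrom = as.character(df[[1]]),
                   start = df[[2]] + 1L, end = df[[3]])
  } else if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     quote = "", stringsAsFactors = FALSE)
    df <- df[df[[3]] == "gene", , drop = FALSE]
    ids <- sub('.*gene_id "([^"]+)".*', "\\1", df[[9]])
    tibble::tibble(gene_id = ids, chrom = as.character(df[[1]]),
                   start = df[[4]], end = df[[5]])
  } else {
    stop("annotation must be .bed or .gtf", call. = FALSE)
  }
}
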
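#' Read genotypes from a VCF file
#'
#' Parses the GT field of a biallelic VCF into 0/1/2 counts of the ALT
#' allele; `./.` (or any missing GT) becomes `NA`. Multi-allelic records
#' are rejected with the offending position.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [genotype_set()] (animals = VCF samples).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop_ssblup("multi-allelic record at ",
                vcfR::getCHROM(v)[multi][1L], ":", vcfR::getPOS(v)[multi][1L],
                class = "ssblup_unsupported_record")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- 0; out[g %in% c("0/1", "1/0")] <- 1; out[g == "1/1"] <- 2
    out
  }
  cnt <- apply(gt, 2L, code)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  cnt <- t(cnt)
  id <- vcfR::getID(v)
  if (all(is.na(id))) id <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  colnames(cnt) <- id
  genotype_set(cnt, data.frame(snp = id, chrom = vcfR::getCHROM(v),
                               pos = vcfR::getPOS(v)))
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF 4.2 file with placeholder REF/ALT alleles (`A`/`B`) and GT
#' as the only FORMAT field, so [read_vcf_genotypes()] round-trips the
#' counts and map exactly.
#'
#' @param geno a [genotype_set()].
#' @param path output path.
#' @export
write_vcf_genotypes <- function(geno, path) {
  cnt <- geno$counts
  gt <- matrix("./.", nrow(cnt), ncol(cnt))
  gt[!is.na(cnt) & cnt == 0] <- "0/0"
  gt[!is.na(cnt) & cnt == 1] <- "0/1"
  gt[!is.na(cnt) & cnt == 2] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(cnt)), collapse = "\t")), con)
  body <- cbind(geno$map$chrom, geno$map$pos, geno$map$snp, "A", "B", ".",
                "PASS", ".", "GT", t(gt))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an allele-count table
#'
#' A plain TSV carrying the SNP map in three comment header lines
#' (`#snp`, `#chrom`, `#pos`) followed by one row per animal
#' (`animal<TAB>counts...`, `NA` for missing). Round-trips exactly with
#' [write_counts_table()].
#'
#' @param path file path.
#' @return a [genotype_set()].
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path, n = 3L)
  assert_that(all(startsWith(lines, c("#snp\t", "#chrom\t", "#pos\t"))),
              "counts table lacks #snp/#chrom/#pos header lines",
              class = "ssblup_format")
  hdr <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][-1])
  df <- utils::read.table(path, sep = "\t", skip = 3L, header = FALSE,
                          colClasses = c("character", rep("numeric", length(hdr[[1]]))))
  cnt <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cnt) <- df[[1L]]
  genotype_set(cnt, data.frame(snp = hdr[[1]], chrom = hdr[[2]],
                               pos = as.numeric(hdr[[3]])))
}

#' @rdname read_counts_table
#' @param geno a [genotype_set()].
#' @export
write_counts_table <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("#snp", geno$map$snp), collapse = "\t"),
               paste(c("#chrom", geno$map$chrom), collapse = "\t"),
               paste(c("#pos", geno$map$pos), collapse = "\t")), con)
  utils::write.table(cbind(rownames(geno$counts), geno$counts), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write phenotype records
#'
#' CSV with columns `animal`, `parity`, `farm_year_month` and one column
#' per trait.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal = "character"))
  assert_that(all(c("animal", "parity", "farm_year_month") %in% names(df)),
              "phenotype file needs animal, parity, farm_year_month columns",
              class = "ssblup_format")
  df
}

#' @rdname read_phenotypes
#' @param records record data frame.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a gene table (BED or GFF/GTF)
#'
#' Thin wrapper over `rtracklayer::import()`; the gene name is taken from
#' the first of `name`, `Name`, `ID`, `gene_id`, `gene_name` present in the
#' metadata columns.
#'
#' @param path file path (`.bed`, `.gff`, `.gff3`, `.gtf`).
#' @return `GRanges` with a `name` metadata column.
#' @export
read_gene_table <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- names(GenomicRanges::mcols(gr))
  nm_col <- intersect(c("name", "Name", "ID", "gene_id", "gene_name"), mc)
  nm <- if (length(nm_col)) as.character(GenomicRanges::mcols(gr)[[nm_col[1]]])
        else paste0("gene", seq_along(gr))
  GenomicRanges::mcols(gr)$name <- nm
  gr
}

#' Minimal TOML reader
#'
#' Supports the subset used by the package's run configurations: `[section]`
#' headers, `key = value` pairs with string (`"..."`), boolean
#' (`true`/`false`), numeric scalars, and flat arrays `[v1, v2, ...]`.
#' Comments start with `#`.
#'
#' @param path TOML file.
#' @return nested named list.
#' @export
read_toml <- function(path) {
  out <- list()
  section <- NULL
  parse_val <- function(v) {
    v <- trimws(v)
    if (startsWith(v, "[")) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (trimws(inner) == "") return(list())
      parts <- strsplit(inner, ",")[[1]]
      return(unlist(lapply(parts, parse_val)))
    }
    if (grepl("^\".*\"$", v)) return(gsub("^\"|\"$", "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (line in readLines(path)) {
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(line, regexpr("=", line), invert = TRUE)[[1]]
    assert_that(length(kv) == 2, "malformed TOML line: ", line,
                class = "ssblup_format")
    key <- trimws(kv[1]); val <- parse_val(kv[2])
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

#' @rdname read_toml
#' @param x nested named list (one level of sections).
#' @export
write_toml <- function(x, path) {
  fmt_val <- function(v) {
    if (is.character(v) && length(v) == 1L) return(sprintf("\"%s\"", v))
    if (is.logical(v) && length(v) == 1L) return(if (v) "true" else "false")
    if (length(v) == 1L) return(format(v, digits = 15))
    paste0("[", paste(vapply(v, fmt_val, ""), collapse = ", "), "]")
  }
  lines <- character(0)
  scalars <- x[!vapply(x, is.list, TRUE)]
  for (k in names(scalars))
    lines <- c(lines, paste(k, "=", fmt_val(scalars[[k]])))
  for (k in names(x)[vapply(x, is.list, TRUE)]) {
    lines <- c(lines, "", sprintf("[%s]", k))
    for (kk in names(x[[k]]))
      lines <- c(lines, paste(kk, "=", fmt_val(x[[k]][[kk]])))
  }
  writeLines(lines, path)
  invisible(path)
}
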
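#' Run configuration with the study's default thresholds
#'
#' Central container for every tunable threshold, with defaults equal to the
#' values used throughout the analysis: minimum within-pool alternative
#' allele frequency 0.10, minimum site score 25, pool fixation threshold
#' 0.001 (0.1% polymorphism), window size 200000 bp, step 10000 bp, region
#' thresholds `sc_max = 0.05` / `si_min = 0.35`, and the S45 exclusion (an
#' amplicon unlinked to the SI phenotype).
#'
#' @param ... named overrides of any default.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(min_freq = 0.10, min_score = 25, fixation_threshold = 0.001,
              window_size = 200000, step_size = 10000,
              sc_max = 0.05, si_min = 0.35, min_windows = 10,
              exclude_alleles = "S45", seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$min_freq >= 0, cfg$min_freq <= 1,
            cfg$fixation_threshold >= 0, cfg$fixation_threshold <= 1,
            cfg$window_size > 0, cfg$step_size > 0)
  structure(cfg, class = "run_config")
}

required_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

allele_token_ok <- function(tok) {
  tok == unknown_marker | grepl("^[A-Za-z0-9_.]+$", tok)
}

#' Read a per-individual S-locus genotype table
#'
#' Tab-separated, one row per individual, columns `individual`, `population`,
#' `srk_alleles`, `b80_alleles`, `phenotype`. Allele lists are
#' comma-separated; `?` marks an unidentified gene copy; `NA` (or empty) is
#' allowed for `b80_alleles` and `phenotype`. Lines starting with `#` are
#' comments. Round-trips byte-identically with [write_genotype_table()] for
#' canonical files.
#'
#' @param path file path.
#' @return data frame with the five columns as character.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                          na.strings = "NA")
  required_columns(df, c("individual", "population", "srk_alleles",
                         "b80_alleles", "phenotype"), "genotype table")
  for (i in seq_len(nrow(df))) {
    toks <- split_alleles(df$srk_alleles[i])
    bad <- toks[!allele_token_ok(toks)]
    if (length(bad))
      stop(sprintf("genotype table line %d: bad allele token '%s'",
                   i + 1L, bad[1]))
  }
  df
}

#' @rdname read_genotype_table
#' @param genotypes genotype data frame.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a B80-to-SRK link map
#'
#' Two-column TSV `b80_hap`, `srk_alleles` (comma-joined set of SRK alleles
#' the B80 haplotype is known to associate with).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_linkmap <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#")
  required_columns(df, c("b80_hap", "srk_alleles"), "link map")
  empty <- !nzchar(df$srk_alleles)
  if (any(empty))
    stop("link map: empty SRK allele set for haplotype ",
         paste(df$b80_hap[empty], collapse = ", "))
  df
}

#' Read population metadata
#'
#' TSV with columns `population`, `tm` (multilocus outcrossing rate),
#' `cluster`, `mating_class` and optional logical `tm_excluded`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_population_meta <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  required_columns(df, c("population", "tm", "cluster", "mating_class"),
                   "population metadata")
  if (is.null(df$tm_excluded)) df$tm_excluded <- FALSE
  df$tm_excluded <- as.logical(df$tm_excluded)
  df
}

#' Read silique-count records of self-pollinations
#'
#' TSV with columns `plant_id`, `full`, `partial`, `empty`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_silique_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required_columns(df, c("plant_id", "full", "partial", "empty"),
                   "silique table")
  df
}

#' Read pooled SNP calls (native TSV or VCF dialect)
#'
#' The native TSV is long format, two rows per site (one per pool):
#' `chrom pos ref al4 pool A C G T depth score is_indel`, with `al4 = NA`
#' when the AL4 allele is unknown. The VCF dialect is VCF 4.x with samples
#' `SC` and `SI`, per-sample `AD` (allele depths over REF+ALT), `DP` and `SQ`
#' (site score), the AL4 allele in `INFO/AL4` and indels flagged by
#' `INFO/INDEL`. Both dialects yield identical call tables for the same
#' data; counts for bases absent from REF/ALT are zero.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return wide data frame, one row per site: `chrom`, `pos`, `ref`, `al4`,
#'   `sc_A` ... `sc_T`, `sc_depth`, `sc_score`, `si_A` ... `si_T`,
#'   `si_depth`, `si_score`, `is_indel`.
#' @export
read_snp_calls <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_snp_calls_tsv(path) else read_snp_calls_vcf(path)
}

read_snp_calls_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", na.strings = "NA",
                          colClasses = c(chrom = "character"))
  required_columns(df, c("chrom", "pos", "ref", "al4", "pool", "A", "C",
                         "G", "T", "depth", "score", "is_indel"),
                   "SNP call table")
  sums <- df$A + df$C + df$G + df$T
  bad <- which(sums != df$depth)
  if (length(bad))
    stop(sprintf("SNP call table: depth != sum of counts at %s:%d (pool %s)",
                 df$chrom[bad[1]], df$pos[bad[1]], df$pool[bad[1]]))
  pivot <- function(pool) {
    sub <- df[toupper(df$pool) == pool, , drop = FALSE]
    sub[order(sub$chrom, sub$pos), , drop = FALSE]
  }
  sc <- pivot("SC"); si <- pivot("SI")
  if (nrow(sc) != nrow(si) || any(sc$chrom != si$chrom) ||
      any(sc$pos != si$pos))
    stop("SNP call table: SC and SI rows do not cover the same sites")
  data.frame(
    chrom = sc$chrom, pos = as.integer(sc$pos), ref = sc$ref, al4 = sc$al4,
    sc_A = sc$A, sc_C = sc$C, sc_G = sc$G, sc_T = sc$T,
    sc_depth = sc$depth, sc_score = sc$score,
    si_A = si$A, si_C = si$C, si_G = si$G, si_T = si$T,
    si_depth = si$depth, si_score = si$score,
    is_indel = as.logical(sc$is_indel),
    stringsAsFactors = FALSE
  )
}

read_snp_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  info <- fix$INFO
  al4 <- ifelse(grepl("(^|;)AL4=[^;]*", info),
                sub(".*(^|;)AL4=([^;]*).*", "\\2", info), NA_character_)
  al4[al4 == "."] <- NA_character_
  is_indel <- grepl("(^|;)INDEL($|;)", info)
  ad <- vcfR::extract.gt(v, element = "AD")
  sq <- vcfR::extract.gt(v, element = "SQ")
  samples <- colnames(ad)
  stopifnot(all(c("SC", "SI") %in% samples))
  n <- nrow(fix)
  alleles <- lapply(seq_len(n), function(i)
    c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]))
  counts_for <- function(sample) {
    m <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
    for (i in seq_len(n)) {
      depths <- as.integer(strsplit(ad[i, sample], ",", fixed = TRUE)[[1]])
      idx <- match(alleles[[i]], BASES)
      ok <- !is.na(idx)
      m[i, idx[ok]] <- depths[ok]
    }
    m
  }
  sc_m <- counts_for("SC"); si_m <- counts_for("SI")
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, al4 = al4,
    sc_A = sc_m[, "A"], sc_C = sc_m[, "C"], sc_G = sc_m[, "G"],
    sc_T = sc_m[, "T"], sc_depth = as.integer(rowSums(sc_m)),
    sc_score = as.numeric(sq[, "SC"]),
    si_A = si_m[, "A"], si_C = si_m[, "C"], si_G = si_m[, "G"],
    si_T = si_m[, "T"], si_depth = as.integer(rowSums(si_m)),
    si_score = as.numeric(sq[, "SI"]),
    is_indel = is_indel,
    stringsAsFactors = FALSE
  )
}

#' Write pooled SNP calls (native TSV or VCF dialect)
#'
#' Deterministic writers for the two dialects read by [read_snp_calls()];
#' `write -> read` is the identity on canonical call tables. The VCF writer
#' emits a minimal VCF 4.2 body with samples SC and SI, `AD`/`DP`/`SQ`
#' format fields and `AL4=`/`INDEL` INFO keys.
#'
#' @param calls wide SNP-call data frame.
#' @param path output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @export
write_snp_calls <- function(calls, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    long <- do.call(rbind, lapply(c("sc", "si"), function(pool) {
      data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                 al4 = calls$al4, pool = toupper(pool),
                 A = calls[[paste0(pool, "_A")]],
                 C = calls[[paste0(pool, "_C")]],
                 G = calls[[paste0(pool, "_G")]],
                 T = calls[[paste0(pool, "_T")]],
                 depth = calls[[paste0(pool, "_depth")]],
                 score = calls[[paste0(pool, "_score")]],
                 is_indel = calls$is_indel,
                 stringsAsFactors = FALSE)
    }))
    long <- long[order(long$chrom, long$pos, long$pool), ]
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AL4,Number=1,Type=String,Description=\"AL4 reference allele\">",
    "##INFO=<ID=INDEL,Number=0,Type=Flag,Description=\"Site is an indel\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SQ,Number=1,Type=Float,Description=\"Site score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSC\tSI"
  )
  body <- vapply(seq_len(nrow(calls)), function(i) {
    ref <- calls$ref[i]
    cnt_sc <- unlist(calls[i, paste0("sc_", BASES)])
    cnt_si <- unlist(calls[i, paste0("si_", BASES)])
    seen <- BASES[cnt_sc > 0 | cnt_si > 0]
    alt <- setdiff(unique(c(seen, calls$al4[i])), c(ref, NA))
    if (length(alt) == 0L) alt <- setdiff(BASES, ref)[1]  # placeholder ALT
    alleles <- c(ref, alt)
    idx <- match(alleles, BASES)
    fmt <- function(cnt, depth, score)
      sprintf("%s:%d:%s", paste(cnt[idx], collapse = ","), depth,
              format(score))
    info <- paste0("AL4=", ifelse(is.na(calls$al4[i]), ".", calls$al4[i]),
                   if (isTRUE(calls$is_indel[i])) ";INDEL" else "")
    paste(calls$chrom[i], calls$pos[i], ".", ref,
          paste(alt, collapse = ","), ".", "PASS", info, "AD:DP:SQ",
          fmt(cnt_sc, calls$sc_depth[i], calls$sc_score[i]),
          fmt(cnt_si, calls$si_depth[i], calls$si_score[i]), sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene annotations (BED, GFF3 or plain TSV)
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' parsed with rtracklayer and converted to the package's 1-based inclusive
#' convention; a plain TSV with columns `gene`, `chrom`, `start`, `end`
#' (1-based inclusive) is read directly.
#'
#' @param path file path.
#' @param format `"bed"`, `"gff3"` or `"tsv"`; guessed from the extension
#'   when missing.
#' @return data frame with `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3", "tsv")
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = c(chrom = "character"))
    required_columns(df, c("gene", "chrom", "start", "end"), "annotation TSV")
    return(df[c("gene", "chrom", "start", "end")])
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read ", format, " annotations")
  gr <- as.data.frame(rtracklayer::import(path, format = format))
  name <- if (format == "bed") gr$name else {
    nm <- gr$Name
    if (is.null(nm)) nm <- gr$ID
    nm
  }
  # rtracklayer already converts BED to 1-based inclusive coordinates
  data.frame(gene = as.character(name),
             chrom = as.character(gr$seqnames),
             start = gr$start, end = gr$end,
             stringsAsFactors = FALSE)
}
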
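#' 1-based inclusive interval length
#'
#' Length in bp of an interval given by its first and last base. All
#' coordinates in this package are 1-based and inclusive (the native GFF3/VCF
#' convention), so the span of the border gene Sopen07g024640
#' (70,111,740..70,120,667) is 8928 bp.
#'
#' @param start,end integer positions, `start <= end`.
#' @return integer length `end - start + 1`.
#' @examples
#' interval_span(70111740, 70120667) # 8928
#' @export
interval_span <- function(start, end) {
  if (any(start > end)) stop("interval_span: start > end")
  as.integer(end - start + 1L)
}

#' Do two 1-based inclusive intervals overlap?
#' @param s1,e1,s2,e2 interval bounds.
#' @return logical.
#' @export
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

#' Parse a "chrom:start-end" region string
#' @param x character scalar such as `"chr7:59085047-59488648"`.
#' @return list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", x)
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start > end) stop("region start > end: ", x)
  list(chrom = m[2], start = start, end = end)
}

## ---- genomes (FASTA) -------------------------------------------------------

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  # keep only the first word of the FASTA header, as aligners do
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome FASTA (wrapped at 60 columns)
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

## ---- gene annotations (GFF3) ----------------------------------------------

#' Construct a gene annotation
#'
#' A gene annotation is a list of two data frames: `genes` with columns
#' `gene_id`, `chrom`, `start`, `end`, `strand`, and `features` with columns
#' `gene_id`, `kind` (`five_prime_UTR`, `CDS`, `three_prime_UTR` or `exon`),
#' `start`, `end`. Coordinates are 1-based inclusive; every feature must lie
#' within its gene and features of one gene must not overlap each other.
#'
#' @param genes,features data frames as described above.
#' @return object of class `gene_annotation`.
#' @export
annotation <- function(genes, features = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("annotation: genes must have columns ", paste(need, collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("annotation: gene with start > end")
  if (is.null(features)) {
    features <- data.frame(gene_id = character(), kind = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    if (any(features$start > features$end)) stop("annotation: feature with start > end")
    gs <- genes$start[match(features$gene_id, genes$gene_id)]
    ge <- genes$end[match(features$gene_id, genes$gene_id)]
    if (anyNA(gs)) stop("annotation: feature for unknown gene_id")
    if (any(features$start < gs | features$end > ge)) {
      stop("annotation: feature outside its gene span")
    }
    for (g in unique(features$gene_id)) {
      f <- features[features$gene_id == g, ]
      f <- f[order(f$start), ]
      if (nrow(f) > 1L && any(f$start[-1L] <= f$end[-nrow(f)])) {
        stop("annotation: overlapping features within gene ", g)
      }
    }
  }
  structure(list(genes = genes, features = features), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$features), "features on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Accepts `gene` records with `five_prime_UTR`/`CDS`/`three_prime_UTR`/`exon`
#' children linked by `Parent`.
#'
#' @param path GFF3 file.
#' @return a [annotation()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  is_gene <- df$type == "gene"
  genes <- data.frame(
    gene_id = as.character(df$ID[is_gene]),
    chrom = as.character(df$seqnames[is_gene]),
    start = df$start[is_gene], end = df$end[is_gene],
    strand = as.character(df$strand[is_gene]),
    stringsAsFactors = FALSE
  )
  kinds <- c("five_prime_UTR", "CDS", "three_prime_UTR", "exon")
  is_feat <- df$type %in% kinds
  parent <- vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  features <- data.frame(
    gene_id = parent[is_feat],
    kind = as.character(df$type[is_feat]),
    start = df$start[is_feat], end = df$end[is_feat],
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  annotation(genes, features)
}

#' Write gene models as GFF3
#' @param ann a [annotation()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  f <- ann$features
  gr_g <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = rep(NA_character_, nrow(g))
  )
  if (nrow(f)) {
    strand_f <- g$strand[match(f$gene_id, g$gene_id)]
    chrom_f <- g$chrom[match(f$gene_id, g$gene_id)]
    gr_f <- GenomicRanges::GRanges(
      chrom_f, IRanges::IRanges(f$start, f$end), strand = strand_f,
      type = f$kind, ID = rep(NA_character_, nrow(f)), Parent = f$gene_id
    )
    gr <- c(gr_g, gr_f)
  } else {
    gr <- gr_g
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

## ---- variants (VCF) --------------------------------------------------------

#' Build a variant table
#'
#' Canonical container for filtered variant calls: one row per variant with
#' `chrom`, 1-based `pos`, `ref`/`alt` allele strings, `var_class`
#' (`SNP` iff both alleles are single bases, else `INDEL`), `genotype_class`
#' (`homozygous`/`heterozygous`) and `mean_depth`.
#'
#' @param chrom,pos,ref,alt,genotype_class,mean_depth vectors, recycled.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          genotype_class = "homozygous",
                          mean_depth = NA_real_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   genotype_class = rep_len(as.character(genotype_class), n),
                   mean_depth = rep_len(as.numeric(mean_depth), n),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$pos < 1L)) stop("variant_table: pos < 1")
  df$var_class <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNP", "INDEL")
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read variants from a VCF
#'
#' Single-sample VCF v4.2. Mean depth is taken from the `DP` INFO field,
#' genotype class from the sample `GT` (het iff the two alleles differ).
#' INDELs are kept left-anchored as given; no re-normalization.
#'
#' @param path VCF (optionally gzipped).
#' @return a [variant_table()].
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(variant_table())
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
  gt <- tryCatch(vcfR::extract.gt(v)[, 1L], error = function(e) rep(NA_character_, n))
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  gclass <- ifelse(is.na(gt), "homozygous",
                   ifelse(a1 == a2, "homozygous", "heterozygous"))
  variant_table(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                ref = fix[, "REF"], alt = fix[, "ALT"],
                genotype_class = gclass, mean_depth = dp)
}

#' Write variants as VCF v4.2
#'
#' Writes a single-sample VCF with `DP` in INFO and `GT` in FORMAT. The file
#' is gzip-compressed (name it `.vcf.gz`).
#'
#' @param variants a [variant_table()].
#' @param path output file path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, sample_name = "sample") {
  n <- nrow(variants)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean depth of coverage\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- matrix(NA_character_, nrow = n, ncol = 8L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(NA_character_, nrow = n, ncol = 2L,
               dimnames = list(NULL, c("FORMAT", sample_name)))
  if (n) {
    fix[, "CHROM"] <- variants$chrom
    fix[, "POS"] <- as.character(variants$pos)
    fix[, "ID"] <- "."
    fix[, "REF"] <- variants$ref
    fix[, "ALT"] <- variants$alt
    fix[, "QUAL"] <- "."
    fix[, "FILTER"] <- "PASS"
    fix[, "INFO"] <- ifelse(is.na(variants$mean_depth), ".",
                            paste0("DP=", variants$mean_depth))
    gt[, "FORMAT"] <- "GT"
    gt[, 2L] <- ifelse(variants$genotype_class == "heterozygous", "0/1", "1/1")
  }
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, path)
  invisible(path)
}

## ---- similarity hits (12-column tabular) ----------------------------------

HIT_COLS <- c("query_id", "subject_id", "identity_pct", "length", "mismatches",
              "gapopens", "qstart", "qend", "sstart", "send", "evalue", "score")

#' Read a 12-column tabular similarity hit table
#'
#' The de-facto tab-separated dialect emitted by protein search tools:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score.
#'
#' @param path tab-separated file, `#` comments allowed.
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L) {
    stop("malformed hit table ", path, ": expected 12 columns, got ", ncol(df))
  }
  names(df) <- HIT_COLS
  if (any(df$evalue < 0)) stop("malformed hit table ", path, ": negative evalue")
  if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
    stop("malformed hit table ", path, ": identity_pct outside [0,100]")
  }
  df
}

#' Write a 12-column tabular hit table
#' @param hits data.frame with the 12 standard columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a minimal hit record table
#' @param query_id,subject_id,score,evalue,identity_pct vectors, recycled.
#' @return data.frame with the 12 standard columns (positions filled with NA).
#' @export
hit_table <- function(query_id, subject_id, score, evalue, identity_pct = NA_real_) {
  data.frame(query_id = query_id, subject_id = subject_id,
             identity_pct = identity_pct, length = NA_integer_,
             mismatches = NA_integer_, gapopens = NA_integer_,
             qstart = NA_integer_, qend = NA_integer_,
             sstart = NA_integer_, send = NA_integer_,
             evalue = evalue, score = score, stringsAsFactors = FALSE)
}

## ---- DEG tables ------------------------------------------------------------

#' Read a differential-expression table
#'
#' Tab-delimited with header; required columns `gene_id`, `logFC`, `fdr`;
#' optional `chrom`, `start`, `end`, `contrast`.
#'
#' @param path file path.
#' @param contrast contrast label (e.g. `"BR"`) stored on the records when
#'   the file carries none.
#' @return data.frame of DEG records.
#' @export
read_deg_table <- function(path, contrast = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "logFC", "fdr")
  if (!all(need %in% names(df))) {
    stop("malformed DEG table ", path, ": needs columns ",
         paste(need, collapse = ", "))
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop("malformed DEG table ", path, ": fdr outside [0,1]")
  }
  if (!is.null(contrast) && is.null(df$contrast)) df$contrast <- contrast
  df
}

#' Write a differential-expression table
#' @param deg data.frame of DEG records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
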
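# Data model and file I/O: SV records, genotype matrices, clade maps,
# RepeatMasker-style tables, chromosome tables, BED masks.

#' Construct a table of structural variant records
#'
#' The unit flowing through every filter is one SV per row: locus, type,
#' length, optional allele sequence and supporting-read count. Coordinates are
#' 1-based inclusive (VCF convention); any BED emitted by this package is
#' 0-based half-open.
#'
#' @param chrom chromosome names.
#' @param pos 1-based start coordinates.
#' @param id unique variant identifiers.
#' @param svtype one of `"INS"`, `"DEL"`, `"INV"`.
#' @param svlen positive length in bp. For `INS` this is the inserted-allele
#'   length; for `DEL`/`INV` it equals `end - pos`.
#' @param end 1-based end coordinate; defaults to `pos` for insertions and
#'   `pos + svlen` otherwise.
#' @param seq optional nucleotide sequence of the variant allele.
#' @param support optional supporting-read count.
#' @return a `data.frame` of class `sv_records`.
#' @export
sv_records <- function(chrom, pos, id, svtype, svlen,
                       end = NULL, seq = NA_character_, support = NA_integer_) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  svtype <- rep_len(as.character(svtype), n)
  svlen <- rep_len(as.integer(svlen), n)
  if (is.null(end)) end <- ifelse(svtype == "INS", pos, pos + svlen)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos), id = as.character(id),
    svtype = as.character(svtype), svlen = as.integer(svlen),
    end = as.integer(end),
    seq = rep_len(as.character(seq), n),
    support = rep_len(as.integer(support), n),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
}

validate_sv_records <- function(df) {
  assert_cols(df, c("chrom", "pos", "id", "svtype", "svlen", "end"), "sv_records")
  if (anyDuplicated(df$id)) stop("duplicate variant ids in sv_records", call. = FALSE)
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad)) stop("svtype outside {INS, DEL, INV}: ", paste(unique(df$svtype[bad]), collapse = ","), call. = FALSE)
  if (any(df$svlen < 1L)) stop("svlen must be >= 1", call. = FALSE)
  span <- df$svtype != "INS"
  if (any(abs((df$end[span] - df$pos[span]) - df$svlen[span]) > 1L)) {
    stop("for DEL/INV, end - pos must equal svlen within 1 bp", call. = FALSE)
  }
  class(df) <- unique(c("sv_records", class(df)))
  df
}

#' Construct a genotype (alt-allele dosage) matrix
#'
#' Rows are variants, columns diploid individuals; entries are alt-allele
#' dosages 0/1/2 with `NA` for a missing call. Missing is a first-class state
#' and is never imputed silently.
#'
#' @param dosage integer matrix with variant ids as rownames and individual
#'   ids as colnames.
#' @return a validated dosage matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs variant rownames and individual colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate variant ids", call. = FALSE)
  if (anyDuplicated(colnames(dosage))) stop("duplicate individual ids", call. = FALSE)
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be in {0, 1, 2, NA}", call. = FALSE)
  class(dosage) <- c("genotype_matrix", class(dosage))
  dosage
}

#' Construct an individual-to-clade assignment map
#'
#' Maps every individual to a population label and one of two clade labels,
#' and carries the per-clade genotyping-error tolerance used when that clade
#' serves as the outgroup in phylogenetic filtering.
#'
#' @param individual,population,clade character vectors of equal length;
#'   `clade` must take exactly the values `"A"` and `"B"`.
#' @param tolerances named integer vector `c(A = ..., B = ...)`. Default
#'   assigns 4 to the larger clade and 2 to the smaller one, matching a
#'   24-versus-8 individual sampling design.
#' @return a `data.frame` of class `clade_map` with a `tolerances` attribute.
#' @export
clade_map <- function(individual, population, clade, tolerances = NULL) {
  if (anyDuplicated(individual)) stop("duplicate individual in clade map", call. = FALSE)
  clade <- as.character(clade)
  if (!all(clade %in% c("A", "B"))) stop("clade labels must be 'A' or 'B'", call. = FALSE)
  df <- data.frame(individual = as.character(individual),
                   population = as.character(population),
                   clade = clade, stringsAsFactors = FALSE)
  sizes <- table(factor(df$clade, levels = c("A", "B")))
  if (is.null(tolerances)) {
    tolerances <- c(A = 2L, B = 2L)
    tolerances[names(which.max(sizes))] <- 4L
  }
  tolerances <- vapply(tolerances[c("A", "B")], as.integer, integer(1))
  names(tolerances) <- c("A", "B")
  if (anyNA(tolerances) || any(tolerances < 0L)) stop("tolerances must be non-negative integers for both clades", call. = FALSE)
  attr(df, "tolerances") <- tolerances
  class(df) <- unique(c("clade_map", class(df)))
  df
}

#' @rdname clade_map
#' @param map a `clade_map`.
#' @param which clade label.
#' @export
clade_individuals <- function(map, which) map$individual[map$clade == which]

#' @rdname clade_map
#' @export
clade_tolerance <- function(map, which) unname(attr(map, "tolerances")[which])

# ---- VCF ----

gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(!a %in% 0:1)) return(NA_integer_)
    sum(a)
  }, integer(1))
}

#' Read a structural-variant VCF with per-individual genotypes
#'
#' Parses a VCF 4.x file whose records carry `SVTYPE` (and usually `SVLEN`,
#' `END`) INFO keys and `GT` FORMAT fields. Records with `SVTYPE` outside
#' `{INS, DEL, INV}` (e.g. breakends or translocations) and multi-allelic
#' records are skipped with logged counts. Genotypes `./.` and half-calls such
#' as `./1` map to missing; `0/1`, `1/0` and `0|1` all map to dosage 1.
#'
#' Insertion length is taken from `|SVLEN|`, falling back to the length of the
#' allele sequence; deletion/inversion length from `END - POS`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a list with elements `records` (an [sv_records] table), `genotypes`
#'   (a [genotype_matrix]) and `skipped` (named counts of skipped records).
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@fix) == 0L) {
    return(list(records = sv_records(character(), integer(), character(),
                                     character(), integer()),
                genotypes = NULL,
                skipped = c(non_sv_type = 0L, multiallelic = 0L)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) || ncol(v@gt) < 2L) {
    stop("VCF has no genotype (GT) columns; genotypes are required", call. = FALSE)
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen  <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  endi   <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  seqinfo <- vcfR::extract.info(v, "SEQ")

  multi <- grepl(",", fix$ALT %||% "")
  keep_type <- !is.na(svtype) & svtype %in% SV_TYPES
  keep <- keep_type & !multi
  skipped <- c(non_sv_type = sum(!keep_type), multiallelic = sum(multi & keep_type))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("GT field absent from FORMAT; genotypes are required", call. = FALSE)

  pos <- as.integer(fix$POS)
  alt <- fix$ALT
  seq <- ifelse(!is.na(seqinfo), seqinfo,
                ifelse(!is.na(alt) & !grepl("^<", alt) & nchar(alt) > 1L,
                       substring(alt, 2L), NA_character_))
  svlen_abs <- abs(svlen)
  len <- ifelse(svtype == "INS",
                ifelse(!is.na(svlen_abs), svlen_abs, nchar(seq)),
                ifelse(!is.na(endi), endi - pos, svlen_abs))
  end <- ifelse(svtype == "INS", pos, ifelse(!is.na(endi), endi, pos + svlen_abs))
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0("sv_", seq_len(nrow(fix)))[noid]

  w <- which(keep)
  if (!length(w)) {
    return(list(records = sv_records(character(), integer(), character(),
                                     character(), integer()),
                genotypes = NULL, skipped = skipped))
  }
  records <- sv_records(chrom = fix$CHROM[w], pos = pos[w], id = ids[w],
                        svtype = svtype[w], svlen = len[w], end = end[w],
                        seq = seq[w],
                        support = suppressWarnings(as.integer(vcfR::extract.info(v, "SUPPORT")))[w])
  dosage <- apply(gt[w, , drop = FALSE], 2, gt_to_dosage)
  dosage <- matrix(as.integer(dosage), nrow = length(w),
                   dimnames = list(records$id, colnames(gt)))
  list(records = records, genotypes = genotype_matrix(dosage), skipped = skipped)
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Write structural variants and genotypes to a VCF 4.2 file
#'
#' Emits symbolic ALT alleles (`<INS>` etc.) with `SVTYPE`, `SVLEN`, `END` and,
#' when available, `SEQ` in INFO, plus a `GT` column per individual.
#' [read_sv_vcf()] inverts it exactly (round-trip identity on records and
#' dosages).
#'
#' @param records an [sv_records] table.
#' @param genotypes a [genotype_matrix] whose rownames equal `records$id`
#'   (same order), or `NULL` for a site-only file with a placeholder sample.
#' @param path output path.
#' @param chrom_table optional chromosome-length table used to emit contig
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, genotypes, path, chrom_table = NULL) {
  if (!is.null(genotypes)) {
    if (!identical(rownames(genotypes), records$id)) {
      stop("genotype matrix rownames do not match record ids", call. = FALSE)
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svclades",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End coordinate">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting read count">',
    '##INFO=<ID=SEQ,Number=1,Type=String,Description="Variant allele sequence">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(chrom_table)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chrom_table$chrom, chrom_table$length))
  }
  samples <- if (is.null(genotypes)) character() else colnames(genotypes)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- hdr
  if (nrow(records)) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", records$svtype,
                    ifelse(records$svtype == "DEL", -records$svlen, records$svlen),
                    records$end)
    has_sup <- !is.na(records$support)
    info[has_sup] <- paste0(info[has_sup], ";SUPPORT=", records$support[has_sup])
    has_seq <- !is.na(records$seq)
    info[has_seq] <- paste0(info[has_seq], ";SEQ=", records$seq[has_seq])
    body <- paste(records$chrom, records$pos, records$id, "N",
                  paste0("<", records$svtype, ">"), ".", "PASS", info, "GT",
                  sep = "\t")
    if (!is.null(genotypes)) {
      gt <- apply(genotypes, 2, dosage_to_gt)
      gt <- matrix(gt, nrow = nrow(records))
      body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- RepeatMasker-style tables ----

#' Map a RepeatMasker class/family string onto the coarse repeat taxonomy
#'
#' Tandem = simple + low-complexity + satellite + rRNA/tRNA/macrosatellite;
#' interspersed classes keep their own labels (LTR, LINE/CR1, SINE, DNA).
#'
#' @param x character vector of RepeatMasker `class/family` strings.
#' @return character vector over
#'   `{tandem, LTR, LINE/CR1, SINE, DNA, other, no_match}`.
#' @export
repeat_class_of <- function(x) {
  out <- rep("other", length(x))
  x0 <- toupper(x)
  out[grepl("SIMPLE|LOW_COMPLEXITY|SATELLITE|RRNA|TRNA|SNRNA|MACROSAT", x0)] <- "tandem"
  out[grepl("^LTR", x0)] <- "LTR"
  out[grepl("^LINE", x0)] <- "LINE/CR1"
  out[grepl("^SINE", x0)] <- "SINE"
  out[grepl("^DNA", x0)] <- "DNA"
  out[is.na(x) | x == ""] <- "no_match"
  out
}

#' Read a repeat-annotation table (RepeatMasker .out or TSV)
#'
#' Accepts the classic whitespace-delimited RepeatMasker `.out` dialect (three
#' header lines; query name interpreted as the variant id) or a TSV fallback
#' with columns `variant_id`, `repeat_name`, `repeat_class`, `overlap_bp`,
#' `score`. Overlap is the query-interval length `qend - qbegin + 1`. Rows
#' with negative coordinates are rejected with a warning.
#'
#' @param path input path.
#' @return a `data.frame` with columns `variant_id`, `repeat_name`,
#'   `repeat_class`, `overlap_bp`, `score`.
#' @export
read_repeat_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) && grepl("variant_id", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    assert_cols(df, c("variant_id", "repeat_name", "repeat_class", "overlap_bp"), "repeat TSV")
    if (is.null(df$score)) df$score <- NA_real_
    bad <- df$overlap_bp < 0
    if (any(bad)) {
      warning(sum(bad), " repeat row(s) with negative overlap rejected")
      df <- df[!bad, , drop = FALSE]
    }
    return(df[, c("variant_id", "repeat_name", "repeat_class", "overlap_bp", "score")])
  }
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(variant_id = character(), repeat_name = character(),
                      repeat_class = character(), overlap_bp = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  parse_row <- function(f) {
    if (length(f) < 11L) return(NULL)
    qb <- suppressWarnings(as.integer(f[6])); qe <- suppressWarnings(as.integer(f[7]))
    if (is.na(qb) || is.na(qe)) return(NULL)
    data.frame(variant_id = f[5], repeat_name = f[10],
               repeat_class = repeat_class_of(f[11]),
               overlap_bp = qe - qb + 1L,
               qbegin = qb,
               score = suppressWarnings(as.numeric(f[1])),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, Filter(Negate(is.null), lapply(fields, parse_row)))
  if (is.null(rows)) rows <- data.frame(variant_id = character(), repeat_name = character(),
                                        repeat_class = character(), overlap_bp = integer(),
                                        qbegin = integer(), score = numeric())
  bad <- rows$qbegin < 0 | rows$overlap_bp < 1L
  if (any(bad)) {
    warning(sum(bad), " repeat row(s) with negative/invalid coordinates rejected")
    rows <- rows[!bad, , drop = FALSE]
  }
  rows$qbegin <- NULL
  rows
}

#' Write a repeat-annotation TSV
#' @param matches data.frame as returned by [read_repeat_table()].
#' @param path output path.
#' @export
write_repeat_table <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Clade map / chromosome table / BED ----

#' Read a clade assignment map from YAML or TSV
#'
#' The YAML layout is
#' ```yaml
#' tolerances: {A: 2, B: 4}
#' individuals:
#'   - {id: ind01, population: pop1, clade: A}
#' ```
#' The TSV layout has columns `individual`, `population`, `clade`. When the
#' file sets no tolerances, the defaults of [clade_map()] apply.
#'
#' @param path input path.
#' @return a [clade_map].
#' @export
read_clade_map <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    ind <- y$individuals
    if (is.null(ind)) stop("clade map YAML lacks an 'individuals' block", call. = FALSE)
    get <- function(field) vapply(ind, function(i) {
      v <- i[[field]]
      if (is.null(v)) stop("clade map entry missing field '", field, "'", call. = FALSE)
      as.character(v)
    }, character(1))
    tol <- if (!is.null(y$tolerances)) unlist(y$tolerances) else NULL
    clade_map(get("id"), get("population"), get("clade"), tolerances = tol)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    assert_cols(df, c("individual", "population", "clade"), "clade map TSV")
    clade_map(df$individual, df$population, df$clade)
  }
}

#' Write a clade map to YAML
#' @param map a [clade_map].
#' @param path output path.
#' @export
write_clade_map <- function(map, path) {
  tol <- attr(map, "tolerances")
  y <- list(
    tolerances = as.list(as.integer(tol)),
    individuals = lapply(seq_len(nrow(map)), function(i) {
      list(id = map$individual[i], population = map$population[i], clade = map$clade[i])
    })
  )
  names(y$tolerances) <- names(tol)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a chromosome-length table (TSV: name, length)
#' @param path input path.
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_chrom_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  chrom_table(df$chrom, df$length)
}

#' Construct a chromosome-length table
#' @param chrom chromosome names.
#' @param length lengths in bp (positive).
#' @return data.frame with columns `chrom`, `length`.
#' @export
chrom_table <- function(chrom, length) {
  length <- as.numeric(length)
  if (any(length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names", call. = FALSE)
  data.frame(chrom = as.character(chrom), length = length, stringsAsFactors = FALSE)
}

#' Read a BED file of intervals into 1-based inclusive coordinates
#' @param path BED path (0-based half-open on disk).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
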
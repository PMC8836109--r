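## Readers and writers: PED pedigrees, annotated variant tables, aligned
## FASTA, funnel reports.

## Canonical annotation-table headers, in file order: internal field ->
## column header. Genotype columns are headed by the member id itself.
.COLUMN_MAP <- c(
  chrom = "Chrom", pos = "Pos", ref = "Ref", alt = "Alt", gene = "Gene",
  exonic_classification = "ExonicClassification",
  region_class = "RegionClass", qual = "Qual", depth = "Depth",
  maf_1kg = "MAF_1KG", maf_exac_nontcga = "MAF_ExAC_nonTCGA",
  maf_gnomad_nfe = "MAF_gnomAD_NFE", local_cohort_freq = "LocalCohortFreq",
  cadd_phred = "CADD_PHRED", gerp = "GERP", phylop = "PhyloP",
  phastcons = "PhastCons",
  intolerance_inhouse = "Intolerance_InHouse",
  intolerance_esp = "Intolerance_ESP",
  intolerance_exac = "Intolerance_ExAC",
  z_score = "ZScore", pli = "pLI",
  SIFT = "SIFT", Polyphen2_HumDiv = "Polyphen2_HumDiv",
  Polyphen2_HumVar = "Polyphen2_HumVar", LRT = "LRT",
  MutationTaster = "MutationTaster", MutationAssessor = "MutationAssessor",
  FATHMM = "FATHMM", MetaSVM = "MetaSVM", MetaLR = "MetaLR",
  VEST3 = "VEST3", PROVEAN = "PROVEAN",
  ReliabilityIndex = "ReliabilityIndex"
)

.MANDATORY_COLUMNS <- c("Chrom", "Pos", "Ref", "Alt", "Gene",
                        "ExonicClassification", "RegionClass", "Qual",
                        "Depth")

.NUMERIC_FIELDS <- c("pos", "qual", "depth", "maf_1kg", "maf_exac_nontcga",
                     "maf_gnomad_nfe", "local_cohort_freq", "cadd_phred",
                     "gerp", "phylop", "phastcons", "intolerance_inhouse",
                     "intolerance_esp", "intolerance_exac", "z_score", "pli",
                     "VEST3", "ReliabilityIndex")

#' Canonical annotation-table column manifest
#'
#' The tab-separated annotation table is expected to carry these headers
#' (an artifact convention in the spirit of ANNOVAR output), plus one
#' genotype column per sequenced family member headed by the member
#' identifier, plus any number of uninterpreted passthrough columns.
#' `"."` and the empty string denote a missing value in any field.
#'
#' @return Named character vector: internal field name -> column header.
#' @export
annotationManifest <- function() .COLUMN_MAP

## Missing-token handling -------------------------------------------------------

.na_token <- function(x) {
  x <- trimws(as.character(x))
  x[x == "." | x == ""] <- NA_character_
  x
}

## Genotype token vocabulary (unphased only).
.GT_TOKENS <- c(
  "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het", "1/1" = "hom_alt",
  "./." = "missing",
  "ref" = "hom_ref", "het" = "het", "hom" = "hom_alt",
  "hom_ref" = "hom_ref", "hom_alt" = "hom_alt", "missing" = "missing"
)
.GT_WRITE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")

.parseGenotypes <- function(tokens, member, lines) {
  tok <- .na_token(tokens)
  tok[is.na(tok)] <- "./."
  out <- .GT_TOKENS[tolower(tok)]
  ## VCF-style tokens keep their case; lowercase covers the word synonyms
  raw <- .GT_TOKENS[tok]
  out[is.na(out)] <- raw[is.na(out)]
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("malformed genotype token '%s' for member '%s' (line %d)",
                 tokens[bad[1L]], member, lines[bad[1L]]))
  unname(out)
}

.normalizeClassification <- function(x, region, lines) {
  tok <- .na_token(x)
  norm <- gsub("[ -]+", "_", tolower(tok))
  syn <- c(
    nonsynonymous_snv = "nonsynonymous_snv", nonsyn_snv = "nonsynonymous_snv",
    synonymous_snv = "synonymous_snv", syn_snv = "synonymous_snv",
    frameshift_deletion = "frameshift_deletion",
    frameshift_insertion = "frameshift_insertion",
    nonframeshift = "nonframeshift",
    nonframeshift_deletion = "nonframeshift",
    nonframeshift_insertion = "nonframeshift",
    nonframeshift_substitution = "nonframeshift",
    stopgain = "stopgain", stoploss = "stoploss",
    unknown = "unknown", noncoding = "noncoding"
  )
  out <- unname(syn[norm])
  ## a missing classification on a coding variant is 'unknown' (retained by
  ## the non-synonymous stage); on non-coding rows it is 'noncoding'
  miss <- is.na(norm)
  out[miss] <- ifelse(region[miss] %in% c("exonic", "splicing"),
                      "unknown", "noncoding")
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("unrecognized exonic classification '%s' (line %d)",
                 tok[bad[1L]], lines[bad[1L]]))
  out
}

.normalizeRegion <- function(x, lines) {
  tok <- .na_token(x)
  norm <- gsub("[ ;].*$", "", tolower(tok))  # keep first of multi-annotations
  norm[grepl("^utr", norm)] <- "utr"
  norm[norm %in% c("upstream", "downstream", "ncrna_exonic",
                   "ncrna_intronic")] <- "other"
  out <- ifelse(norm %in% .REGION_CLASSES, norm, NA_character_)
  bad <- which(is.na(out) & !is.na(tok))
  if (length(bad))
    stop(sprintf("unrecognized region class '%s' (line %d)",
                 tok[bad[1L]], lines[bad[1L]]))
  out[is.na(tok)] <- "other"
  out
}

## Pedigree ---------------------------------------------------------------------

#' Build a pedigree from member vectors
#'
#' @param member_id,father_id,mother_id Member and parent identifiers
#'   (`NA` or `"0"` for an absent parent).
#' @param sex `male`, `female` or `unknown` (or PED codes 1/2/0).
#' @param phenotype `crc_case`, `polyp` or `unaffected`.
#' @param age_at_event Age at diagnosis (cases/polyps) or recruitment.
#' @param role Carrier-expectation roles; derived from phenotype via the
#'   default [segregationPolicy()] when `NULL`.
#' @return A [Pedigree][Pedigree-class].
#' @export
pedigree <- function(member_id, father_id = NA, mother_id = NA,
                     sex = "unknown", phenotype = "unaffected",
                     age_at_event = NA, role = NULL) {
  n <- length(member_id)
  norm_parent <- function(p) {
    p <- rep_len(as.character(p), n)
    p[!is.na(p) & p %in% c("0", ".")] <- NA_character_
    p
  }
  sexmap <- c("1" = "male", "2" = "female", "0" = "unknown",
              male = "male", female = "female", unknown = "unknown")
  sex <- unname(sexmap[tolower(rep_len(as.character(sex), n))])
  if (any(is.na(sex))) stop("invalid sex code")
  m <- data.frame(
    member_id = as.character(member_id),
    father_id = norm_parent(father_id),
    mother_id = norm_parent(mother_id),
    sex = sex,
    phenotype = rep_len(as.character(phenotype), n),
    age_at_event = suppressWarnings(as.integer(rep_len(age_at_event, n))),
    role = if (is.null(role)) rep(NA_character_, n)
           else rep_len(as.character(role), n),
    stringsAsFactors = FALSE
  )
  ped <- new("Pedigree", members = transform(m, role = ifelse(
    is.na(role), "uninformative", role)))
  if (is.null(role)) ped <- assignRoles(ped) else validObject(ped)
  ped
}

#' Read an extended PED pedigree file
#'
#' Parses a white-space separated PED file with the 6 standard columns
#' (family, member, father, mother, sex, affection) plus two extension
#' columns: a phenotype role keyword (`crc_case`/`crc`, `polyp`/`cp`,
#' `unaffected`) and an age (`.` for unknown). Parent identifier `0` means
#' no recorded parent; a non-zero parent must be present in the file.
#'
#' @param path Path of the PED file.
#' @return A [Pedigree][Pedigree-class] with roles assigned by the default
#'   [segregationPolicy()].
#' @examples
#' ped <- readPedigree(system.file("extdata", "crc_family.ped",
#'                                 package = "VariantFunnel"))
#' roles(ped)
#' @export
readPedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(pedigree(character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 8L))
    stop(sprintf("expected 8 columns in PED file, found %d (line %d)",
                 nf[nf != 8L][1L], which(nf != 8L)[1L]))
  m <- do.call(rbind, fields)
  phenmap <- c(crc_case = "crc_case", crc = "crc_case", case = "crc_case",
               polyp = "polyp", cp = "polyp", unaffected = "unaffected")
  phen <- unname(phenmap[tolower(m[, 7L])])
  if (any(is.na(phen)))
    stop(sprintf("unrecognized phenotype keyword '%s' (line %d)",
                 m[which(is.na(phen))[1L], 7L], which(is.na(phen))[1L]))
  age <- .na_token(m[, 8L])
  pedigree(member_id = m[, 2L], father_id = m[, 3L], mother_id = m[, 4L],
           sex = m[, 5L], phenotype = phen, age_at_event = age)
}

#' Write a pedigree in the extended PED dialect
#'
#' @param ped A [Pedigree][Pedigree-class].
#' @param path Output path.
#' @param family_id Family identifier for column 1.
#' @export
writePedigree <- function(ped, path, family_id = "FAM1") {
  m <- ped@members
  sexmap <- c(male = "1", female = "2", unknown = "0")
  aff <- ifelse(m$phenotype == "unaffected", "1", "2")
  out <- data.frame(
    family_id, m$member_id,
    ifelse(is.na(m$father_id), "0", m$father_id),
    ifelse(is.na(m$mother_id), "0", m$mother_id),
    sexmap[m$sex], aff, m$phenotype,
    ifelse(is.na(m$age_at_event), ".", m$age_at_event)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Annotated table --------------------------------------------------------------

#' Read a tab-separated annotated variant table
#'
#' Parses a table in the canonical column layout (see
#' [annotationManifest()]): one row per variant, `"."`/empty as missing,
#' genotype columns headed by pedigree member identifiers, and unknown
#' extra columns preserved as passthrough. Every row is either parsed into
#' a typed record or rejected with a line-numbered error; invariants
#' (position at least 1, differing alleles, frequencies and PhastCons in
#' \[0, 1\]) are enforced at load.
#'
#' @param path Path of the TSV file.
#' @param ped The [Pedigree][Pedigree-class] whose member identifiers label
#'   the genotype columns.
#' @return A [VariantTable][VariantTable-class].
#' @export
readAnnotatedTable <- function(path, ped) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(.MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  .buildVariantTable(raw, ped, source = path)
}

## Shared by the reader and the simulator: raw character data.frame with
## canonical headers -> validated VariantTable.
.buildVariantTable <- function(raw, ped, source = NA_character_) {
  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1
  members <- memberIds(ped)
  gcols <- intersect(names(raw), members)
  known <- unname(.COLUMN_MAP)
  extra <- setdiff(names(raw), c(known, members))

  v <- data.frame(row.names = NULL)
  v <- stats::setNames(
    as.data.frame(matrix(nrow = n, ncol = 0)), character(0))
  for (f in names(.COLUMN_MAP)) {
    col <- .COLUMN_MAP[[f]]
    x <- if (col %in% names(raw)) .na_token(raw[[col]])
         else rep(NA_character_, n)
    if (f %in% .NUMERIC_FIELDS) {
      num <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(num))
      if (length(bad))
        stop(sprintf("malformed numeric value '%s' in column %s (line %d)",
                     x[bad[1L]], col, lines[bad[1L]]))
      v[[f]] <- num
    } else {
      v[[f]] <- x
    }
  }
  if (n) {
    if (any(is.na(v$chrom) | is.na(v$pos) | is.na(v$ref) | is.na(v$alt))) {
      bad <- which(is.na(v$chrom) | is.na(v$pos) | is.na(v$ref) |
                   is.na(v$alt))[1L]
      stop(sprintf("incomplete variant coordinates (line %d)", lines[bad]))
    }
    if (any(v$pos < 1)) {
      bad <- which(v$pos < 1)[1L]
      stop(sprintf("position must be >= 1, found %s (line %d)",
                   v$pos[bad], lines[bad]))
    }
    if (any(v$ref == v$alt)) {
      bad <- which(v$ref == v$alt)[1L]
      stop(sprintf("ref and alt alleles are identical (line %d)",
                   lines[bad]))
    }
    v$region_class <- .normalizeRegion(v$region_class, lines)
    v$exonic_classification <- .normalizeClassification(
      v$exonic_classification, v$region_class, lines)
  }
  v$pos <- as.integer(v$pos)
  v$depth <- as.integer(v$depth)

  g <- matrix("missing", nrow = n, ncol = length(gcols),
              dimnames = list(NULL, gcols))
  for (mcol in gcols)
    g[, mcol] <- .parseGenotypes(raw[[mcol]], mcol, lines)

  pt <- raw[, extra, drop = FALSE]
  new("VariantTable", variants = v, genotypes = g, passthrough = pt,
      manifest = names(raw), source = source)
}

#' Write an annotated variant table
#'
#' Emits the canonical tab-separated layout: annotation columns per
#' [annotationManifest()], one VCF-style genotype column per member
#' (`0/0`, `0/1`, `1/1`, `./.`), then passthrough columns. Missing values
#' are written as `"."`. Reading the file back with
#' [readAnnotatedTable()] reproduces all typed fields.
#'
#' @param x A [VariantTable][VariantTable-class].
#' @param path Output path.
#' @export
writeAnnotatedTable <- function(x, path) {
  stopifnot(is(x, "VariantTable"))
  v <- x@variants
  out <- data.frame(row.names = NULL, check.names = FALSE,
                    matrix(nrow = nrow(v), ncol = 0))
  for (f in names(.COLUMN_MAP)) {
    val <- v[[f]]
    chr <- if (is.numeric(val)) vapply(val, function(z) {
      if (is.na(z)) "." else format(z, digits = 15, scientific = FALSE)
    }, character(1)) else ifelse(is.na(val), ".", as.character(val))
    out[[.COLUMN_MAP[[f]]]] <- chr
  }
  for (mcol in colnames(x@genotypes))
    out[[mcol]] <- unname(.GT_WRITE[x@genotypes[, mcol]])
  for (pcol in names(x@passthrough))
    out[[pcol]] <- ifelse(is.na(x@passthrough[[pcol]]), ".",
                          as.character(x@passthrough[[pcol]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Alignment audit --------------------------------------------------------------

#' Read a pre-aligned protein FASTA
#'
#' @param path Path of an aligned amino-acid FASTA (gap character `-`);
#'   all sequences must have equal length.
#' @return A [Biostrings::AAStringSet] holding the alignment block.
#' @export
readAlignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) && length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows have unequal lengths; input must be pre-aligned")
  aln
}

#' Cross-species identity of one alignment column
#'
#' Fraction of non-reference sequences whose residue at a 1-based column
#' equals the reference residue; gaps never match. A value of 1 means the
#' audited residue is identical across all aligned species, the signature
#' of strong evolutionary constraint at a candidate missense position.
#'
#' @param block An alignment as returned by [readAlignment()] (an
#'   `AAStringSet` of equal-width sequences).
#' @param column 1-based column index within the alignment.
#' @param reference_id Name of the reference sequence (e.g. the human
#'   entry).
#' @return Fraction in \[0, 1\].
#' @examples
#' aln <- readAlignment(system.file("extdata",
#'     "ptk7_ig4_synthetic_alignment.fasta", package = "VariantFunnel"))
#' columnIdentity(aln, 26, "human")
#' @export
columnIdentity <- function(block, column, reference_id) {
  if (!length(block)) stop("empty alignment")
  wid <- Biostrings::width(block)[1L]
  if (column < 1L || column > wid)
    stop(sprintf("column %d out of range (alignment width %d)",
                 column, wid))
  if (!reference_id %in% names(block))
    stop("reference id '", reference_id, "' not in alignment")
  col <- vapply(as.character(block), substr, character(1), column, column)
  refres <- col[[reference_id]]
  others <- col[setdiff(names(block), reference_id)]
  if (!length(others)) stop("alignment has no non-reference sequences")
  mean(others == refres & others != "-" & refres != "-")
}

## Funnel report I/O ------------------------------------------------------------

#' Write and read a funnel report
#'
#' The report file is simultaneously human-readable and machine-readable:
#' a commented header embedding the configuration as YAML, then a
#' tab-separated table with columns `stage`, `count` and the
#' comma-separated surviving variant identifiers. `readFunnelReport()`
#' restores the object losslessly. A report whose counts are not
#' non-increasing is refused.
#'
#' @param report A [FunnelReport][FunnelReport-class].
#' @param path File path.
#' @return `readFunnelReport()` returns the restored `FunnelReport`.
#' @export
writeFunnelReport <- function(report, path) {
  stopifnot(is(report, "FunnelReport"))
  validObject(report)
  cfg <- lapply(.configFields(), function(f) slot(report@config, f))
  names(cfg) <- .configFields()
  hdr <- c("# VariantFunnel funnel report",
           paste0("#cfg ", strsplit(yaml::as.yaml(cfg), "\n")[[1L]]))
  s <- report@stages
  surv <- vapply(s$stage, function(st)
    paste(report@survivors[[st]], collapse = ","), character(1))
  body <- c("stage\tcount\tsurvivors",
            sprintf("%s\t%d\t%s", s$stage, s$count, surv))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeFunnelReport
#' @export
readFunnelReport <- function(path) {
  lines <- readLines(path)
  cfgl <- sub("^#cfg ", "", lines[grepl("^#cfg ", lines)])
  cfg <- do.call(filterConfig, yaml::yaml.load(paste(cfgl, collapse = "\n")))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character")
  stages <- data.frame(stage = tab$stage, count = as.integer(tab$count),
                       stringsAsFactors = FALSE)
  survivors <- lapply(tab$survivors, function(s)
    if (is.na(s) || s == "") character(0) else strsplit(s, ",")[[1L]])
  names(survivors) <- tab$stage
  new("FunnelReport", stages = stages, survivors = survivors, config = cfg)
}
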
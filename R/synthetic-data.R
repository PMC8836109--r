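## Seeded generator of annotated family variant datasets: Mendelian
## gene-dropping through the pedigree, annotation scores from benign-like
## and deleterious-like regimes spanning the funnel thresholds.

#' The six-member colorectal cancer family template
#'
#' The sequenced family the pipeline's defaults emulate: an affected
#' mother (I-2, colorectal cancer at 60), two affected offspring (II-1 and
#' II-4, cancer at 41 and 44), two offspring with colorectal polyps
#' diagnosed in their forties (II-2, II-6), and one young unaffected
#' grandchild (III-2, recruited at 23, below the family's earliest onset
#' age). Unsequenced spouses are recorded as absent parents; during gene
#' dropping their transmitted allele is drawn from the population
#' frequency. Sexes of the sibship are not part of the published pedigree
#' summary and are fixed here as an arbitrary convention.
#'
#' @return A [Pedigree][Pedigree-class] with default roles assigned
#'   (cases obligate, polyp patients optional, unaffected uninformative).
#' @examples
#' crcFamilyPedigree()
#' @export
crcFamilyPedigree <- function() {
  pedigree(
    member_id = c("I-2", "II-1", "II-2", "II-4", "II-6", "III-2"),
    father_id = c(NA, NA, NA, NA, NA, "II-4"),
    mother_id = c(NA, "I-2", "I-2", "I-2", "I-2", NA),
    sex = c("female", "male", "female", "male", "female", "male"),
    phenotype = c("crc_case", "crc_case", "polyp", "crc_case", "polyp",
                  "unaffected"),
    age_at_event = c(60L, 41L, 45L, 44L, 46L, 23L)
  )
}

#' Default benign-like and deleterious-like score regimes
#'
#' Distribution parameters for the two annotation regimes the background
#' mixture draws from. The deleterious-like regime centers every score
#' comfortably on the passing side of the default thresholds (CADD ~
#' N(25, 4), GERP and PhyloP ~ N(4, 1), PhastCons ~ Beta(8, 1),
#' intolerance scores ~ N(-1, 0.5), Z ~ N(2, 1), pLI ~ Beta(9, 0.5),
#' predictor calls favorable with probability 0.85); the benign-like
#' regime centers below them (CADD ~ N(5, 3) truncated at 0, GERP ~
#' N(0, 1.5), PhyloP ~ N(0, 1), PhastCons ~ Beta(1, 3), intolerance ~
#' N(0.5, 0.5), Z ~ N(-0.5, 1), pLI ~ Beta(0.5, 2), favorable
#' probability 0.2). Both regimes have mass on both sides of every
#' threshold, so each filter stage is genuinely exercised.
#'
#' @return Named list with elements `benign` and `deleterious`.
#' @export
defaultScoreRegimes <- function() {
  list(
    benign = list(cadd = c(5, 3), gerp = c(0, 1.5), phylop = c(0, 1),
                  phastcons = c(1, 3), intol = c(0.5, 0.5),
                  z = c(-0.5, 1), pli = c(0.5, 2), favorable_prob = 0.2),
    deleterious = list(cadd = c(25, 4), gerp = c(4, 1), phylop = c(4, 1),
                       phastcons = c(8, 1), intol = c(-1, 0.5),
                       z = c(2, 1), pli = c(9, 0.5),
                       favorable_prob = 0.85)
  )
}

#' Construct simulation parameters
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_background Number of background variants (default 5000).
#' @param pedigree Pedigree template (default [crcFamilyPedigree()]).
#' @param freq_range Founder alternate-allele frequency range; per-variant
#'   frequencies are drawn log-uniformly within it (default 5e-5 to 2e-3,
#'   emulating a rare-variant pool that has largely passed population
#'   frequency screening while keeping a tail above the MAF cap so the
#'   frequency stage is exercised).
#' @param score_regimes See [defaultScoreRegimes()].
#' @param fraction_deleterious_background Probability that a background
#'   variant draws its scores from the deleterious-like regime
#'   (default 0.1).
#' @param planted List of [plantedVariant()] specifications.
#' @return A [SimulationParams][SimulationParams-class].
#' @export
simulationParams <- function(seed, n_background = 5000L,
                             pedigree = crcFamilyPedigree(),
                             freq_range = c(5e-5, 2e-3),
                             score_regimes = defaultScoreRegimes(),
                             fraction_deleterious_background = 0.1,
                             planted = list()) {
  new("SimulationParams",
      seed = as.integer(seed),
      n_background = as.integer(n_background),
      pedigree = pedigree,
      freq_range = as.numeric(freq_range),
      score_regimes = score_regimes,
      fraction_deleterious_background =
        as.numeric(fraction_deleterious_background),
      planted = planted)
}

#' Specify a planted (known-positive) variant
#'
#' Describes one variant inserted into the synthetic table with exactly
#' the given carrier set and annotations. The annotation defaults pass
#' every default threshold, so a planted variant whose carrier set covers
#' all obligate carriers is recoverable by the funnel by construction.
#'
#' @param chrom,pos,ref,alt,gene Variant coordinates and gene symbol.
#' @param carriers Member identifiers carrying the variant (het).
#' @param exonic_classification,region_class Functional classification.
#' @param qual,depth Call quality and coverage.
#' @param maf_1kg,maf_exac_nontcga,maf_gnomad_nfe,local_cohort_freq
#'   Frequency fields (`NA` = absent from the reference population).
#' @param cadd_phred,gerp,phylop,phastcons Per-position scores.
#' @param intolerance_inhouse,intolerance_esp,intolerance_exac,z_score,pli
#'   Gene-level intolerance panel.
#' @param predictors Named list of deleteriousness panel calls; defaults
#'   to an all-favorable panel.
#' @return A planted-variant specification (named list).
#' @export
plantedVariant <- function(chrom, pos, ref, alt, gene, carriers,
                           exonic_classification = "nonsynonymous_snv",
                           region_class = "exonic",
                           qual = 60, depth = 30,
                           maf_1kg = NA_real_,
                           maf_exac_nontcga = NA_real_,
                           maf_gnomad_nfe = NA_real_,
                           local_cohort_freq = NA_real_,
                           cadd_phred = 25, gerp = 4, phylop = 4,
                           phastcons = 1,
                           intolerance_inhouse = -1,
                           intolerance_esp = -1,
                           intolerance_exac = -1,
                           z_score = 2, pli = 0.95,
                           predictors = list(
                             SIFT = "D", Polyphen2_HumDiv = "D",
                             Polyphen2_HumVar = "D", LRT = "D",
                             MutationTaster = "D",
                             MutationAssessor = "H", FATHMM = "D",
                             MetaSVM = "D", MetaLR = "D", VEST3 = 0.9,
                             PROVEAN = "D", ReliabilityIndex = 9)) {
  list(chrom = as.character(chrom), pos = as.integer(pos),
       ref = ref, alt = alt, gene = gene,
       carriers = as.character(carriers),
       exonic_classification = exonic_classification,
       region_class = region_class, qual = qual, depth = depth,
       maf_1kg = maf_1kg, maf_exac_nontcga = maf_exac_nontcga,
       maf_gnomad_nfe = maf_gnomad_nfe,
       local_cohort_freq = local_cohort_freq,
       cadd_phred = cadd_phred, gerp = gerp, phylop = phylop,
       phastcons = phastcons,
       intolerance_inhouse = intolerance_inhouse,
       intolerance_esp = intolerance_esp,
       intolerance_exac = intolerance_exac,
       z_score = z_score, pli = pli, predictors = predictors)
}

## Gene dropping ---------------------------------------------------------------

## Topological order of members (parents before children); errors on a
## cyclic parentage graph.
.pedigreeOrder <- function(ped) {
  m <- ped@members
  ids <- m$member_id
  done <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- vapply(remaining, function(id) {
      row <- m[m$member_id == id, ]
      ok <- function(p) is.na(p) || p %in% done
      ok(row$father_id) && ok(row$mother_id)
    }, logical(1))
    if (!any(ready))
      stop("cyclic pedigree: no member with resolved parents among ",
           paste(remaining, collapse = ", "))
    done <- c(done, remaining[ready])
    remaining <- remaining[!ready]
  }
  done
}

## Vectorized gene drop: one founder allele frequency per variant.
## Returns an integer alternate-allele dosage matrix (variants x members).
.geneDropDosage <- function(ped, freqs) {
  n <- length(freqs)
  ord <- .pedigreeOrder(ped)
  m <- ped@members
  D <- matrix(0L, nrow = n, ncol = nrow(m),
              dimnames = list(NULL, m$member_id))
  transmit <- function(parent_id) {
    ## one allele per variant: from the parent's dosage if recorded in the
    ## pedigree, otherwise from the population (unsequenced spouse)
    if (is.na(parent_id))
      stats::rbinom(n, 1L, freqs)
    else
      stats::rbinom(n, 1L, D[, parent_id] / 2)
  }
  for (id in ord) {
    row <- m[m$member_id == id, ]
    if (is.na(row$father_id) && is.na(row$mother_id)) {
      D[, id] <- stats::rbinom(n, 2L, freqs)
    } else {
      D[, id] <- transmit(row$father_id) + transmit(row$mother_id)
    }
  }
  D
}

#' Drop one variant's genotypes through the pedigree
#'
#' Mendelian gene dropping: founders draw two alleles binomially from the
#' founder allele frequency; each offspring inherits one allele from each
#' parent uniformly at random. A parent absent from the pedigree is
#' treated as a population founder.
#'
#' @param ped A [Pedigree][Pedigree-class].
#' @param founder_allele_freq Alternate-allele frequency in founders.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @return Named character vector of genotype states per member.
#' @examples
#' geneDrop(crcFamilyPedigree(), 0.5, seed = 1)
#' @export
geneDrop <- function(ped, founder_allele_freq, seed = NULL) {
  stopifnot(is(ped, "Pedigree"),
            founder_allele_freq >= 0, founder_allele_freq <= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- .geneDropDosage(ped, founder_allele_freq)
  stats::setNames(c("hom_ref", "het", "hom_alt")[D[1L, ] + 1L],
                  colnames(D))
}

## Dataset generation -----------------------------------------------------------

.sampleCategorical <- function(favorable, fav_codes, unfav_codes) {
  out <- character(length(favorable))
  nf <- sum(favorable)
  out[favorable] <- sample(fav_codes, nf, replace = TRUE)
  out[!favorable] <- sample(unfav_codes, length(out) - nf, replace = TRUE)
  out
}

.PREDICTOR_CODES <- list(
  SIFT = list(fav = "D", unfav = "T"),
  Polyphen2_HumDiv = list(fav = c("D", "P"), unfav = "B"),
  Polyphen2_HumVar = list(fav = c("D", "P"), unfav = "B"),
  LRT = list(fav = "D", unfav = c("N", "U")),
  MutationTaster = list(fav = c("D", "A"), unfav = c("N", "P")),
  MutationAssessor = list(fav = c("H", "M"), unfav = c("L", "N")),
  FATHMM = list(fav = "D", unfav = "T"),
  MetaSVM = list(fav = "D", unfav = "T"),
  MetaLR = list(fav = "D", unfav = "T"),
  PROVEAN = list(fav = "D", unfav = "N")
)

## Zero-row data.frame with the canonical typed columns.
.emptyVariantFrame <- function() {
  v <- data.frame(chrom = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  gene = character(0),
                  exonic_classification = character(0),
                  region_class = character(0), qual = numeric(0),
                  depth = integer(0), stringsAsFactors = FALSE)
  for (f in c("maf_1kg", "maf_exac_nontcga", "maf_gnomad_nfe",
              "local_cohort_freq", "cadd_phred", "gerp", "phylop",
              "phastcons", "intolerance_inhouse", "intolerance_esp",
              "intolerance_exac", "z_score", "pli"))
    v[[f]] <- numeric(0)
  for (p in setdiff(.PREDICTORS, c("VEST3", "ReliabilityIndex")))
    v[[p]] <- character(0)
  v$VEST3 <- numeric(0)
  v$ReliabilityIndex <- numeric(0)
  v
}

#' Generate a synthetic annotated family variant dataset
#'
#' Emits an annotated variant table with the statistical structure the
#' funnel assumes: background variants with genotypes dropped Mendelianly
#' through the pedigree under the null of no linkage to disease, and
#' annotation scores drawn from a benign-like/deleterious-like mixture;
#' planted variants carry exactly their specified carrier sets and
#' annotations. Deleteriousness predictor calls are emitted only for
#' non-synonymous SNVs (mirroring dbNSFP coverage); conservation and
#' gene-level scores are missing for a small fraction of rows.
#'
#' @param params A [SimulationParams][SimulationParams-class].
#' @return A list with elements `table` (a
#'   [VariantTable][VariantTable-class]), `pedigree`, and `truth` (a
#'   [SyntheticTruth][SyntheticTruth-class] naming the planted variants).
#' @examples
#' sim <- generateDataset(simulationParams(seed = 1, n_background = 100))
#' nVariants(sim$table)
#' @export
generateDataset <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  ped <- params@pedigree
  members <- memberIds(ped)
  for (spec in params@planted) {
    bad <- setdiff(spec$carriers, members)
    if (length(bad))
      stop("planted carrier id not in pedigree: ",
           paste(bad, collapse = ", "))
  }
  set.seed(params@seed)
  n <- params@n_background

  v <- data.frame(matrix(nrow = n, ncol = 0))
  g <- matrix("hom_ref", nrow = n, ncol = length(members),
              dimnames = list(NULL, members))
  if (n > 0L) {
    bases <- c("A", "C", "G", "T")
    refi <- sample.int(4L, n, replace = TRUE)
    alti <- (refi - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
    region <- sample(c("intergenic", "intronic", "exonic", "utr",
                       "splicing", "other"), n, replace = TRUE,
                     prob = c(0.44, 0.40, 0.10, 0.03, 0.01, 0.02))
    cls <- rep("noncoding", n)
    exonic <- region == "exonic"
    cls[exonic] <- sample(
      c("nonsynonymous_snv", "synonymous_snv", "frameshift_deletion",
        "frameshift_insertion", "stopgain", "stoploss", "nonframeshift",
        "unknown"), sum(exonic), replace = TRUE,
      prob = c(0.50, 0.35, 0.03, 0.02, 0.02, 0.01, 0.02, 0.05))
    cls[region == "splicing"] <- "unknown"

    lfr <- log(params@freq_range)
    f <- exp(stats::runif(n, lfr[1L], lfr[2L]))
    withNA <- function(x, p_missing)
      ifelse(stats::runif(n) < p_missing, NA_real_, x)
    popmaf <- function() withNA(
      pmin(f * stats::rlnorm(n, 0, 0.25), 1), 0.15)

    delet <- stats::runif(n) < params@fraction_deleterious_background
    reg <- params@score_regimes
    mix <- function(field, draw) {
      out <- numeric(n)
      for (which in c("benign", "deleterious")) {
        sel <- if (which == "deleterious") delet else !delet
        out[sel] <- draw(reg[[which]][[field]], sum(sel))
      }
      out
    }
    rnorm2 <- function(p, k) stats::rnorm(k, p[1L], p[2L])
    rbeta2 <- function(p, k) stats::rbeta(k, p[1L], p[2L])

    v <- data.frame(
      chrom = as.character(sample.int(22L, n, replace = TRUE)),
      pos = sample.int(100000000L, n, replace = TRUE),
      ref = bases[refi], alt = bases[alti],
      gene = sprintf("GENE%04d", sample.int(2000L, n, replace = TRUE)),
      exonic_classification = cls, region_class = region,
      qual = pmax(round(stats::rnorm(n, 60, 20), 1), 0),
      depth = as.integer(stats::rnbinom(n, mu = 40, size = 5)),
      maf_1kg = popmaf(), maf_exac_nontcga = popmaf(),
      maf_gnomad_nfe = popmaf(),
      local_cohort_freq = withNA(pmin(f * stats::rlnorm(n, 0.4, 0.5), 1),
                                 0.3),
      cadd_phred = withNA(pmax(mix("cadd", rnorm2), 0), 0.05),
      gerp = withNA(mix("gerp", rnorm2), 0.1),
      phylop = withNA(mix("phylop", rnorm2), 0.1),
      phastcons = withNA(mix("phastcons", rbeta2), 0.1),
      stringsAsFactors = FALSE
    )
    geneNA <- stats::runif(n) < 0.15  # gene-level panel jointly missing
    for (field in c("intolerance_inhouse", "intolerance_esp",
                    "intolerance_exac"))
      v[[field]] <- ifelse(geneNA, NA_real_, mix("intol", rnorm2))
    v$z_score <- ifelse(geneNA, NA_real_, mix("z", rnorm2))
    v$pli <- ifelse(geneNA, NA_real_, mix("pli", rbeta2))

    fav_p <- ifelse(delet, reg$deleterious$favorable_prob,
                    reg$benign$favorable_prob)
    nsyn <- cls == "nonsynonymous_snv"
    for (p in .PREDICTORS) {
      col <- rep(NA_character_, n)
      fav <- stats::runif(n) < fav_p
      if (p == "VEST3") {
        num <- ifelse(fav, stats::runif(n, 0.5, 1),
                      stats::runif(n, 0, 0.499))
        col[nsyn] <- format(round(num[nsyn], 3))
      } else if (p == "ReliabilityIndex") {
        num <- ifelse(fav, sample(5:10, n, replace = TRUE),
                      sample(1:4, n, replace = TRUE))
        col[nsyn] <- as.character(num[nsyn])
      } else {
        codes <- .PREDICTOR_CODES[[p]]
        calls <- .sampleCategorical(fav, codes$fav, codes$unfav)
        col[nsyn] <- calls[nsyn]
      }
      v[[p]] <- col
    }
    v$VEST3 <- suppressWarnings(as.numeric(v$VEST3))
    v$ReliabilityIndex <- suppressWarnings(as.numeric(v$ReliabilityIndex))

    D <- .geneDropDosage(ped, f)
    g <- matrix(c("hom_ref", "het", "hom_alt")[D + 1L], nrow = n,
                dimnames = list(NULL, members))
  } else {
    v <- .emptyVariantFrame()
  }

  planted_ids <- character(0)
  for (spec in params@planted) {
    row <- data.frame(
      chrom = spec$chrom, pos = spec$pos, ref = spec$ref, alt = spec$alt,
      gene = spec$gene,
      exonic_classification = spec$exonic_classification,
      region_class = spec$region_class,
      qual = spec$qual, depth = as.integer(spec$depth),
      maf_1kg = spec$maf_1kg, maf_exac_nontcga = spec$maf_exac_nontcga,
      maf_gnomad_nfe = spec$maf_gnomad_nfe,
      local_cohort_freq = spec$local_cohort_freq,
      cadd_phred = spec$cadd_phred, gerp = spec$gerp,
      phylop = spec$phylop, phastcons = spec$phastcons,
      intolerance_inhouse = spec$intolerance_inhouse,
      intolerance_esp = spec$intolerance_esp,
      intolerance_exac = spec$intolerance_exac,
      z_score = spec$z_score, pli = spec$pli,
      stringsAsFactors = FALSE
    )
    for (p in .PREDICTORS) {
      val <- spec$predictors[[p]]
      row[[p]] <- if (is.null(val)) NA else val
    }
    row$VEST3 <- suppressWarnings(as.numeric(row$VEST3))
    row$ReliabilityIndex <- suppressWarnings(as.numeric(row$ReliabilityIndex))
    grow <- matrix("hom_ref", nrow = 1L, ncol = length(members),
                   dimnames = list(NULL, members))
    grow[1L, spec$carriers] <- "het"
    v <- rbind(v[, names(row), drop = FALSE], row)
    g <- rbind(g, grow)
    planted_ids <- c(planted_ids,
                     paste(spec$chrom, spec$pos, spec$ref, spec$alt,
                           sep = "_"))
  }

  tab <- new("VariantTable", variants = v, genotypes = g,
             passthrough = data.frame(matrix(nrow = nrow(v), ncol = 0)),
             manifest = unname(.COLUMN_MAP), source = NA_character_)
  validObject(tab)
  truth <- new("SyntheticTruth", planted_ids = planted_ids,
               params = params)
  list(table = tab, pedigree = ped, truth = truth)
}
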
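#' Default UroSEEK mutation panel
#'
#' Returns the queried mutation positions for the two sequencing assays: a
#' ten-gene multiplex panel (FGFR3, TP53, CDKN2A, ERBB2, HRAS, KRAS, PIK3CA,
#' MET, VHL, MLL) and the singleplex TERT-promoter assay restricted to the
#' three promoter hotspots g.1295228, g.1295250 and g.1295242 (hg19, chr5).
#' The multiplex positions are synthetic stand-ins placed inside each gene's
#' hg19 footprint; the TERT hotspot coordinates are the real ones. Alternate
#' alleles are fixed per position so that substitution-class summaries are
#' well defined; TP53 and HRAS carry an excess of A:T>T:A sites, mirroring
#' the transversion-rich spectra seen in aristolochic-acid-exposed cohorts.
#'
#' @return A data.frame with one row per queried mutation: `gene`, `chrom`,
#'   `pos` (1-based hg19), `ref`, `alt`, `assay` (`"multiplex"` or `"tert"`),
#'   and `key` (a `chrom:pos:ref:alt` identifier).
#' @export
default_panel <- function() {
  genes <- list(
    #          chrom  start of synthetic hotspot block
    FGFR3  = c("chr4",  1803568),
    TP53   = c("chr17", 7577058),
    CDKN2A = c("chr9",  21971120),
    ERBB2  = c("chr17", 37880219),
    HRAS   = c("chr11", 533872),
    KRAS   = c("chr12", 25398280),
    PIK3CA = c("chr3",  178936082),
    MET    = c("chr7",  116411990),
    VHL    = c("chr3",  10183718),
    MLL    = c("chr11", 118352430)
  )
  # number of queried positions per gene, weighted toward the genes that
  # dominate urothelial mutation spectra (TP53, FGFR3)
  n_pos <- c(FGFR3 = 9, TP53 = 16, CDKN2A = 5, ERBB2 = 5, HRAS = 4,
             KRAS = 5, PIK3CA = 6, MET = 4, VHL = 3, MLL = 3)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(names(genes), function(g) {
    chrom <- genes[[g]][1]
    start <- as.integer(genes[[g]][2])
    k <- n_pos[[g]]
    pos <- start + seq_len(k) * 7L  # spaced positions within the amplicons
    # deterministic ref/alt assignment (no RNG): cycle substitution classes,
    # with TP53/HRAS enriched for A>T transversions
    idx <- seq_len(k)
    if (g %in% c("TP53", "HRAS")) {
      ref <- ifelse(idx %% 2 == 1, "A", c("C", "G", "C", "G")[(idx %/% 2 - 1) %% 4 + 1])
      alt <- ifelse(ref == "A", "T", ifelse(ref == "C", "T", "A"))
    } else {
      ref <- bases[(idx - 1) %% 4 + 1]
      alt <- bases[(idx %% 4) + 1]
    }
    data.frame(gene = g, chrom = chrom, pos = pos, ref = ref, alt = alt,
               assay = "multiplex", stringsAsFactors = FALSE)
  })
  tert <- data.frame(
    gene = "TERT", chrom = "chr5",
    pos = c(1295228L, 1295250L, 1295242L),
    ref = "G", alt = "A",  # C>T on the coding strand; reported on plus strand
    assay = "tert", stringsAsFactors = FALSE
  )
  panel <- rbind(do.call(rbind, rows), tert)
  panel$key <- mutation_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  rownames(panel) <- NULL
  panel
}

#' Build a mutation key identifier
#'
#' @param chrom,pos,ref,alt Vectors describing single-nucleotide variants
#'   (`pos` 1-based hg19).
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
mutation_key <- function(chrom, pos, ref, alt) {
  stopifnot(all(ref != alt))
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Default chromosome-arm map for the repeat-amplicon aneuploidy assay
#'
#' Assigns loci uniformly to the 39 non-acrocentric autosomal chromosome
#' arms (all 22 q arms plus every p arm except those of the acrocentric
#' chromosomes 13, 14, 15, 21 and 22). The full-scale assay amplifies
#' ~38,000 L1-retrotransposon loci; the default here is a down-scaled map
#' with 100 loci per arm (3,900 total), configurable via `loci_per_arm`.
#'
#' @param loci_per_arm Integer number of loci assigned to each arm.
#' @return A data.frame with columns `locus_id`, `chrom`, `arm`.
#' @export
default_arm_map <- function(loci_per_arm = 100L) {
  stopifnot(loci_per_arm >= 10L)
  arms <- autosomal_arms()
  data.frame(
    locus_id = sprintf("L1_%s_%04d", rep(arms, each = loci_per_arm),
                       rep(seq_len(loci_per_arm), times = length(arms))),
    chrom = rep(sub("[pq]$", "", arms), each = loci_per_arm),
    arm = rep(arms, each = loci_per_arm),
    stringsAsFactors = FALSE
  )
}

#' The 39 non-acrocentric autosomal chromosome arms
#' @return Character vector of arm names (e.g. `"1p"`, `"8q"`).
#' @export
autosomal_arms <- function() {
  acrocentric <- c(13, 14, 15, 21, 22)
  p <- paste0(setdiff(1:22, acrocentric), "p")
  q <- paste0(1:22, "q")
  arms <- c(p, q)
  arms[order(as.integer(sub("[pq]$", "", arms)), sub("^[0-9]+", "", arms))]
}

#' Default identity-check SNP panel
#'
#' Thirty-one common biallelic SNPs on chromosomes 10 and 20, amplified by
#' 26 primers in the wet assay, used to verify that paired samples (e.g.
#' urine and tumor from the same patient) share a genotype. Positions and
#' allele frequencies here are synthetic stand-ins with realistic common
#' minor-allele frequencies.
#'
#' @return A data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf` (population minor-allele frequency used by the simulator).
#' @export
default_snp_panel <- function() {
  n10 <- 16L; n20 <- 15L
  maf <- rep(c(0.18, 0.25, 0.32, 0.41, 0.47), length.out = n10 + n20)
  data.frame(
    snp_id = sprintf("snp%02d", seq_len(n10 + n20)),
    chrom = c(rep("chr10", n10), rep("chr20", n20)),
    pos = c(5000000L + seq_len(n10) * 911L, 3000000L + seq_len(n20) * 877L),
    ref = rep(c("A", "C", "G", "T"), length.out = n10 + n20),
    alt = rep(c("G", "T", "A", "C"), length.out = n10 + n20),
    maf = maf,
    stringsAsFactors = FALSE
  )
}
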
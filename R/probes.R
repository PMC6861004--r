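#' Construct an antisense probe record
#'
#' Sequences are stored in the DNA (T) alphabet as conventionally printed;
#' the transcribed RNA view is available via [probe_sequence()].  Label
#' sites are the U residues of the transcript (T in the stored view),
#' which carry the aminoallyl modification used for dye conjugation.  For
#' targeted probes the 5' end of the probe pairs with the higher mRNA
#' coordinate (`site_5p`), the 3' end with the lower (`site_3p`),
#' 1-based inclusive, so `site_5p - site_3p + 1` equals the probe length.
#'
#' @param name probe name.
#' @param sequence nucleotide string (A/C/G/T/U), 5'->3'.
#' @param target_name targeted transcript, or `NA` for untargeted strands.
#' @param site_5p,site_3p 1-based mRNA coordinates paired with the probe's
#'   5' and 3' ends (`NA` for untargeted strands).
#' @param dye fluorophore name, optional.
#' @param is_control logical: no-intracellular-target control probe.
#' @return a `probe_record`.
#' @export
probe_record <- function(name, sequence, target_name = NA_character_,
                         site_5p = NA_integer_, site_3p = NA_integer_,
                         dye = NA_character_, is_control = FALSE) {
  seq_dna <- toupper(gsub("U", "T", toupper(sequence)))
  if (!grepl("^[ACGT]+$", seq_dna))
    stopf("sequence of '%s' contains non-nucleotide characters", name)
  if (!is.na(site_5p) && !is.na(site_3p)) {
    if (abs(site_5p - site_3p) + 1L != nchar(seq_dna))
      stopf("'%s': |site_5p - site_3p| + 1 (%d) must equal the sequence length (%d)",
            name, abs(site_5p - site_3p) + 1L, nchar(seq_dna))
  }
  structure(
    list(name = name, sequence = seq_dna, target_name = target_name,
         site_5p = site_5p, site_3p = site_3p,
         label_sites = count_label_sites(seq_dna),
         dye = dye, is_control = isTRUE(is_control)),
    class = "probe_record")
}

#' @export
print.probe_record <- function(x, ...) {
  tgt <- if (!is.na(x$site_5p))
    sprintf("%s sites %s-%s",
            if (is.na(x$target_name)) "target" else x$target_name,
            x$site_5p, x$site_3p)
  else if (x$is_control) "(control, no target)" else ""
  cat(sprintf("probe %s: 5'-%s-3' (%d nt, %d label sites) %s\n",
              x$name, x$sequence, nchar(x$sequence), x$label_sites, tgt))
  invisible(x)
}

#' RNA or DNA view of a probe sequence
#' @param probe a [probe_record()].
#' @param as `"rna"` or `"dna"`.
#' @export
probe_sequence <- function(probe, as = c("rna", "dna")) {
  stopifnot(inherits(probe, "probe_record"))
  as <- match.arg(as)
  if (as == "dna") probe$sequence else gsub("T", "U", probe$sequence)
}

#' Count aminoallyl label sites (U/T residues) of a probe
#'
#' One-and two-labeled probes are optimal; three or more risk
#' fluorescence quenching (see [validate_probe()]).
#'
#' @param probe a [probe_record()] or a nucleotide string.
#' @return integer count of U (RNA view) / T (DNA view) residues.
#' @export
count_label_sites <- function(probe) {
  s <- if (inherits(probe, "probe_record")) probe$sequence else
    toupper(gsub("U", "T", toupper(probe)))
  lengths(regmatches(s, gregexpr("T", s)))
}

#' Design an antisense probe against a target mRNA region
#'
#' Returns the reverse complement of `target[start..end]` as a 5'->3'
#' probe.  Following the descending printed convention, the probe's 5'
#' end pairs with the downstream coordinate: `site_5p = end`,
#' `site_3p = start`.
#'
#' @param target_mrna target sequence (character, `RNAString` or
#'   `DNAString`), 5'->3'.
#' @param start,end 1-based inclusive coordinates of the target region.
#' @param name probe name.
#' @return a [probe_record()].
#' @export
antisense_probe <- function(target_mrna, start, end, name = "probe") {
  tgt <- as_dna_string(target_mrna)
  L <- Biostrings::nchar(tgt)
  if (start < 1 || end > L || start > end)
    stopf("coordinates [%d, %d] out of range for a target of length %d",
          start, end, L)
  region <- Biostrings::subseq(tgt, start, end)
  probe <- as.character(Biostrings::reverseComplement(region))
  probe_record(name, probe, target_name = attr(target_mrna, "name") %||% NA,
               site_5p = as.integer(end), site_3p = as.integer(start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dna_string <- function(x) {
  if (inherits(x, "DNAString")) return(x)
  if (inherits(x, "RNAString")) return(Biostrings::DNAString(
    gsub("U", "T", as.character(x))))
  s <- toupper(gsub("U", "T", toupper(as.character(x))))
  if (!grepl("^[ACGT]+$", s))
    stopf("target sequence contains non-nucleotide characters")
  Biostrings::DNAString(s)
}

#' Validate a probe against a target mRNA
#'
#' Locates the longest exact antisense match of the probe in the target
#' and reports the resulting duplex length, whether it reaches the
#' minimum of 18 bp that the dsRNA-binding domain requires for a robust
#' interaction, mismatch positions over the full probe footprint at the
#' matched locus, and the label-site class (`optimal` for 1--2 labels,
#' `quench_risk` for 3 or more, `unlabeled` for none).  Probes with no
#' antisense match of at least `min_match` bp are reported as having no
#' target (the control-probe case).
#'
#' @param probe a [probe_record()].
#' @param target_mrna target sequence, 5'->3'.
#' @param min_match shortest antisense match still reported as a hit, bp.
#' @return a `validation_report`: `has_target`, `duplex_length`,
#'   `match_start`/`match_end` (target coordinates), `mismatch_positions`
#'   (1-based along the probe), `complementarity`, `min_length_ok`,
#'   `label_sites`, `label_site_class`.
#' @export
validate_probe <- function(probe, target_mrna, min_match = 8L) {
  stopifnot(inherits(probe, "probe_record"))
  tgt <- as_dna_string(target_mrna)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe$sequence)))
  n <- nchar(rc)
  hit <- NULL
  for (L in seq(n, min_match)) {
    for (off in seq_len(n - L + 1L)) {
      sub <- substr(rc, off, off + L - 1L)
      m <- Biostrings::matchPattern(sub, tgt)
      if (length(m) > 0) {
        hit <- list(len = L, off = off, start = Biostrings::start(m)[1])
        break
      }
    }
    if (!is.null(hit)) break
  }
  cls <- label_site_class(probe$label_sites)
  if (is.null(hit)) {
    return(structure(list(
      has_target = FALSE, duplex_length = 0L,
      match_start = NA_integer_, match_end = NA_integer_,
      mismatch_positions = integer(0), complementarity = "no_target",
      min_length_ok = FALSE, label_sites = probe$label_sites,
      label_site_class = cls), class = "validation_report"))
  }
  # align the full-length antisense sequence at the matched locus and
  # count mismatches over the overlapping footprint
  full_start <- hit$start - (hit$off - 1L)
  tgt_chars <- strsplit(as.character(tgt), "")[[1]]
  rc_chars <- strsplit(rc, "")[[1]]
  mism <- integer(0)
  for (i in seq_len(n)) {
    pos <- full_start + i - 1L
    if (pos < 1 || pos > length(tgt_chars)) next
    if (tgt_chars[pos] != rc_chars[i]) mism <- c(mism, i)
  }
  # mismatch positions reported along the probe (5'->3'): antisense index
  # i corresponds to probe position n - i + 1
  mism_probe <- sort(n - mism + 1L)
  structure(list(
    has_target = TRUE, duplex_length = hit$len,
    match_start = hit$start, match_end = hit$start + hit$len - 1L,
    mismatch_positions = mism_probe,
    complementarity = if (hit$len == n) "exact" else "mismatched",
    min_length_ok = hit$len >= 18L,
    label_sites = probe$label_sites,
    label_site_class = cls), class = "validation_report")
}

label_site_class <- function(n_sites) {
  if (n_sites == 0) "unlabeled"
  else if (n_sites <= 2) "optimal"
  else "quench_risk"
}

#' @export
print.validation_report <- function(x, ...) {
  if (!x$has_target) {
    cat("no antisense target found\n")
  } else {
    cat(sprintf("duplex %d bp at target %d-%d (%s), min length %s; %d label sites (%s)\n",
                x$duplex_length, x$match_start, x$match_end,
                x$complementarity,
                if (x$min_length_ok) "ok" else "BELOW 18 bp",
                x$label_sites, x$label_site_class))
  }
  invisible(x)
}

#' The validated probe set shipped with the package
#'
#' The seven 20-mer probes used throughout the assay development
#' (beta-actin, MHC-alpha, MLC2a, three NKX2-5 probes and a no-target
#' control probe) plus the auxiliary single-stranded RNAs used in the
#' gel-shift and affinity-purification experiments, with their printed
#' target coordinates (descending: probe 5' end pairs with the higher
#' mRNA coordinate).
#'
#' @param include_auxiliary also return the non-probe ssRNA strands.
#' @return list of [probe_record()]s.
#' @export
probe_catalog <- function(include_auxiliary = TRUE) {
  probes <- list(
    probe_record("beta-actin", "GGATAGCACAGCCTGGATAG",
                 target_name = "ACTB", site_5p = 507L, site_3p = 488L),
    probe_record("MHCa", "GGCACCAATGTCACGGCTCT",
                 target_name = "MYH6", site_5p = 5864L, site_3p = 5845L),
    probe_record("MLC2a", "GGCCTGCTTGGTGGCTGCCA",
                 target_name = "MYL7", site_5p = 66L, site_3p = 47L),
    probe_record("NKX2-5 probe 1", "GGCTGCGCTGCTGCTGTTCC",
                 target_name = "NKX2-5", site_5p = 308L, site_3p = 289L),
    probe_record("NKX2-5 probe 2", "GGACGTGAGTTTCAGCACGC",
                 target_name = "NKX2-5", site_5p = 766L, site_3p = 747L),
    probe_record("NKX2-5 probe 3", "GCGTTATAACCGTAGGGATT",
                 target_name = "NKX2-5", site_5p = 984L, site_3p = 965L),
    probe_record("control", "GGATCGTGACTAGATCGTCA", is_control = TRUE))
  if (include_auxiliary) {
    probes <- c(probes, list(
      probe_record("gel-shift ssRNA (labeled)", "GGATGAGTCACTGCCTAGCC"),
      probe_record("gel-shift ssRNA (complement)", "GGCTAGGCAGTGACTCATCC"),
      probe_record("spectral-FRET ssRNA (labeled)", "GGAAGTAGCACAGTCCAGAC"),
      probe_record("affinity-purification strand 1", "GAGTCCTTCCACGATAGACC"),
      probe_record("affinity-purification strand 2", "GGTCTATCGTGGAAGGACTC")))
  }
  probes
}

#' Standard T7 promoter sequence
#' @export
T7_PROMOTER <- "TAATACGACTCACTATAG"

#' Build the double-stranded T7 transcription template for a probe
#'
#' The probe is transcribed from an annealed pair of complementary DNA
#' oligos: the sense oligo carries the T7 promoter followed by the
#' probe-encoding sequence; the antisense oligo is its exact reverse
#' complement.
#'
#' @param probe a [probe_record()].
#' @param promoter promoter sequence (DNA, 5'->3').
#' @return list: `sense`, `antisense`, `duplex_length`.
#' @export
build_t7_template <- function(probe, promoter = T7_PROMOTER) {
  stopifnot(inherits(probe, "probe_record"))
  sense <- paste0(promoter, probe$sequence)
  antisense <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sense)))
  list(sense = sense, antisense = antisense,
       duplex_length = nchar(sense))
}
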
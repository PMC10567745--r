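# Splice-region anatomy: HGVS c. parsing and the donor/acceptor taxonomy.
#
# The operational windows across each exon/intron junction are:
#   donor site:    last 3 exonic nt (-3..-1) + first 6 intronic nt (+1..+6),
#                  with the near-invariant GT at intronic +1/+2;
#   acceptor site: last 20 intronic nt (-20..-1) + first 3 exonic nt (+1..+3),
#                  with the near-invariant AG at intronic -2/-1.
# Intronic variants outside both windows are deep intronic; exonic variants
# away from exon edges are "exonic_other". Offsets use the HGVS convention:
# c.N+k is k nucleotides into the intron after coding position N, c.N-k is
# k nucleotides before it.

HGVS_POINT <- "(\\d+)([+-]\\d+)?"

#' Parse an HGVS c. string into coding position, intronic offset and edit
#'
#' Handles substitutions (`c.477+5G>A`), small deletions (`c.100_102del`,
#' `c.477+1_477+4del`), duplications and small insertions. Intronic offsets
#' keep their HGVS sign: `+k` is the k-th intronic nucleotide after an exon,
#' `-k` the k-th before one; exonic positions have offset 0. Deletions that
#' span several positions are summarised by their most splice-proximal
#' affected nucleotide (the endpoint with the smallest absolute intronic
#' offset). Unparseable strings are returned flagged, never dropped.
#'
#' @param hgvs_c Character vector of HGVS c. descriptions.
#' @return A tibble with columns `hgvs_c`, `coding_pos`, `intron_offset`,
#'   `edit`, `parseable`.
#' @export
#' @examples
#' parse_hgvs_offset(c("c.477+5G>A", "c.1224-80G>A", "c.100G>A"))
parse_hgvs_offset <- function(hgvs_c) {
  if (length(hgvs_c) == 0) {
    return(tibble::tibble(hgvs_c = character(0), coding_pos = integer(0),
                          intron_offset = integer(0), edit = character(0),
                          parseable = logical(0)))
  }
  dplyr::bind_rows(lapply(hgvs_c, parse_hgvs_one))
}

parse_hgvs_one <- function(s) {
  unparsed <- tibble::tibble(
    hgvs_c = s, coding_pos = NA_integer_, intron_offset = NA_integer_,
    edit = NA_character_, parseable = FALSE
  )
  if (is.na(s) || !nzchar(s)) return(unparsed)
  body <- sub("^c\\.", "", trimws(s))
  if (identical(body, trimws(s))) return(unparsed)
  # strip internal spaces as seen in free-text transcriptions ("c.477+5 G > A")
  body <- gsub("\\s+", "", body)

  # substitution at a single position: N(+/-k)REF>ALT
  m <- regmatches(body, regexec(paste0("^", HGVS_POINT, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m) > 0) {
    return(tibble::tibble(
      hgvs_c = s,
      coding_pos = as.integer(m[2]),
      intron_offset = offset_int(m[3]),
      edit = paste0(m[4], ">", m[5]),
      parseable = TRUE
    ))
  }

  # single-position del/dup/ins-like edits
  m <- regmatches(body, regexec(paste0("^", HGVS_POINT, "(del|dup)([ACGT]*)$"), body))[[1]]
  if (length(m) > 0) {
    return(tibble::tibble(
      hgvs_c = s,
      coding_pos = as.integer(m[2]),
      intron_offset = offset_int(m[3]),
      edit = paste0(m[4], if (nzchar(m[5])) m[5] else ""),
      parseable = TRUE
    ))
  }

  # ranged edits: N1(+/-k1)_N2(+/-k2)(del|dup|ins...)
  m <- regmatches(body, regexec(
    paste0("^", HGVS_POINT, "_", HGVS_POINT, "(del|dup|ins|delins)([ACGT]*)$"), body))[[1]]
  if (length(m) > 0) {
    p1 <- as.integer(m[2]); o1 <- offset_int(m[3])
    p2 <- as.integer(m[4]); o2 <- offset_int(m[5])
    # most splice-proximal endpoint: prefer the intronic endpoint with the
    # smallest |offset|; a del spanning into the exon keeps the exonic edge.
    if (o1 == 0 && o2 == 0) {
      pos <- p1; off <- 0L
    } else if (o1 != 0 && o2 != 0) {
      pick <- if (abs(o1) <= abs(o2)) 1L else 2L
      pos <- c(p1, p2)[pick]; off <- c(o1, o2)[pick]
    } else {
      # one endpoint exonic: the junction itself is affected; report the
      # exonic (offset 0) endpoint as most proximal
      pick <- if (o1 == 0) 1L else 2L
      pos <- c(p1, p2)[pick]; off <- 0L
    }
    return(tibble::tibble(
      hgvs_c = s, coding_pos = pos, intron_offset = off,
      edit = paste0(m[6], if (nzchar(m[7])) m[7] else ""), parseable = TRUE
    ))
  }

  unparsed
}

offset_int <- function(x) {
  if (is.na(x) || !nzchar(x)) 0L else as.integer(x)
}

#' Classify a parsed variant into the splice-region taxonomy
#'
#' Intronic offsets +1..+6 fall in the donor site and -20..-1 in the acceptor
#' site; intronic positions beyond either window are deep intronic. Exonic
#' variants are assigned to the adjacent site when they lie within the last
#' three nucleotides of an exon (donor side) or the first three (acceptor
#' side), with an `exon_edge` flag at the very first/last nucleotide; other
#' exonic variants are `exonic_other`. The essential GT/AG dinucleotide flag
#' is true exactly at intronic donor +1/+2 and acceptor -2/-1.
#'
#' @param intron_offset Integer vector of signed intronic offsets (0 = exonic).
#' @param exon_boundary_distance Optional signed integer: for exonic variants,
#'   `+k` means the k-th nucleotide from the exon start (1 = first nucleotide,
#'   acceptor side) and `-k` the k-th from the exon end (-1 = last nucleotide,
#'   donor side); `NA` when unknown.
#' @return A tibble with columns `region`, `intron_offset`, `exon_edge`,
#'   `essential_dinucleotide`.
#' @export
classify_region <- function(intron_offset, exon_boundary_distance = NA_integer_) {
  n <- length(intron_offset)
  ebd <- rep_len(as.integer(exon_boundary_distance), n)
  off <- as.integer(intron_offset)
  region <- character(n)
  exon_edge <- logical(n)
  essential <- logical(n)
  for (i in seq_len(n)) {
    o <- off[i]
    if (is.na(o)) {
      region[i] <- NA_character_
      exon_edge[i] <- NA
      essential[i] <- NA
      next
    }
    if (o >= 1 && o <= 6) {
      region[i] <- "donor_site"
      essential[i] <- o <= 2
    } else if (o <= -1 && o >= -20) {
      region[i] <- "acceptor_site"
      essential[i] <- o >= -2
    } else if (o != 0) {
      region[i] <- "deep_intronic"
    } else {
      d <- ebd[i]
      if (!is.na(d) && d <= -1 && d >= -3) {
        region[i] <- "donor_site"
        exon_edge[i] <- d == -1
      } else if (!is.na(d) && d >= 1 && d <= 3) {
        region[i] <- "acceptor_site"
        exon_edge[i] <- d == 1
      } else {
        region[i] <- "exonic_other"
      }
    }
  }
  tibble::tibble(
    region = region,
    intron_offset = off,
    exon_edge = exon_edge,
    essential_dinucleotide = essential
  )
}

#' Infer the splicing mechanism of a classified variant
#'
#' Variants inside a donor or acceptor site weaken an existing site
#' (`site_loss`). Deep intronic and other exonic variants act by creating a
#' new site: they are `site_gain` when a gain-qualifying in silico signal is
#' present (a created-site MaxEntScan score above the gain threshold with an
#' increase above it over the wild-type sequence, or a SpliceAI delta above
#' its threshold), otherwise `ambiguous`.
#'
#' @param region Region labels from [classify_region()].
#' @param mes_ref,mes_alt,spliceai Score vectors (NA = unavailable); a missing
#'   `mes_ref` for a de novo site is treated as 0.
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return Character vector `site_loss` / `site_gain` / `ambiguous`.
#' @export
infer_mechanism <- function(region, mes_ref = NA_real_, mes_alt = NA_real_,
                            spliceai = NA_real_,
                            thresholds = default_thresholds()) {
  n <- length(region)
  mes_ref <- rep_len(as.numeric(mes_ref), n)
  mes_alt <- rep_len(as.numeric(mes_alt), n)
  spliceai <- rep_len(as.numeric(spliceai), n)
  ref0 <- ifelse(is.na(mes_ref), 0, mes_ref)
  mes_gain <- !is.na(mes_alt) &
    mes_alt > thresholds$mes_gain_min &
    (mes_alt - ref0) > thresholds$mes_gain_delta
  sai_gain <- !is.na(spliceai) & spliceai > thresholds$spliceai
  dplyr::case_when(
    region %in% c("donor_site", "acceptor_site") ~ "site_loss",
    region %in% c("deep_intronic", "exonic_other") & (mes_gain | sai_gain) ~ "site_gain",
    TRUE ~ "ambiguous"
  )
}

#' Frame arithmetic for an observed splicing outcome
#'
#' A length-changing splicing outcome (exon skipping, extension, truncation,
#' intron retention, new-exon inclusion) causes a frameshift with a premature
#' termination codon unless the affected length is a multiple of three, in
#' which case it is an in-frame change of `length / 3` amino acids. Intron
#' retention is treated as frameshift/PTC even when in frame, unless the
#' caller asserts the retained sequence is stop-free
#' (`assume_stop_free = TRUE`): a retained intron almost always contains an
#' in-frame stop.
#'
#' @param kind Functional outcome kind (see `FUNCTIONAL_KINDS`).
#' @param affected_length_nt Nucleotides added to / removed from the
#'   transcript; mandatory for length-changing kinds.
#' @param assume_stop_free Assert that an in-frame retained intron contains no
#'   stop codon.
#' @return A tibble with columns `frame` (`frameshift_ptc` / `in_frame_change`
#'   / `none`) and `aa_change` (amino acids added/removed for in-frame
#'   changes, else `NA`).
#' @export
#' @examples
#' frame_consequence("exon_skip", 91)  # frameshift + PTC
#' frame_consequence("exon_skip", 75)  # in-frame, 25 amino acids
frame_consequence <- function(kind, affected_length_nt = NA_real_,
                              assume_stop_free = FALSE) {
  n <- length(kind)
  len <- rep_len(as.numeric(affected_length_nt), n)
  stop_free <- rep_len(as.logical(assume_stop_free), n)
  frame <- rep(NA_character_, n)
  aa <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- kind[i]
    if (is.na(k) || !(k %in% LENGTH_CHANGING_KINDS)) {
      frame[i] <- "none"
      next
    }
    if (is.na(len[i])) {
      stop("functional outcome '", k, "' requires affected_length_nt",
           call. = FALSE)
    }
    if (len[i] == 0) {
      frame[i] <- "none"
    } else if (len[i] %% 3 == 0 &&
               (k != "intron_retention" || isTRUE(stop_free[i]))) {
      frame[i] <- "in_frame_change"
      aa[i] <- len[i] / 3
    } else {
      frame[i] <- "frameshift_ptc"
    }
  }
  tibble::tibble(frame = frame, aa_change = aa)
}

#' Annotate a variant table with splice anatomy
#'
#' Convenience wrapper running [parse_hgvs_offset()], [classify_region()] and
#' [infer_mechanism()] over a variant tibble.
#'
#' @param variants A variant tibble (see [variant_table()]); its optional
#'   `exon_boundary_distance` column (signed distance to the nearest exon
#'   boundary for exonic variants, see [classify_region()]) is used when
#'   present.
#' @param thresholds Threshold list used for gain-signal detection.
#' @return The input with columns `coding_pos`, `intron_offset`, `parseable`,
#'   `region`, `exon_edge`, `essential_dinucleotide`, `mechanism` appended.
#' @export
annotate_anatomy <- function(variants, thresholds = default_thresholds()) {
  parsed <- parse_hgvs_offset(variants$hgvs_c)
  ebd <- if ("exon_boundary_distance" %in% names(variants)) {
    variants$exon_boundary_distance
  } else {
    NA_integer_
  }
  cls <- classify_region(parsed$intron_offset, ebd)
  out <- dplyr::bind_cols(
    variants,
    parsed[, c("coding_pos", "intron_offset", "parseable")],
    cls[, c("region", "exon_edge", "essential_dinucleotide")]
  )
  out$mechanism <- infer_mechanism(out$region, out$mes_ref, out$mes_alt,
                                   out$spliceai, thresholds)
  out
}
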
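#' The 16-residue consensus repeat of bacterial ice nucleation proteins
#'
#' Constructs the consensus description of the INP central-domain repeat.
#' The default pattern is the canonical `GYGSTxTAxxxSxLxA` unit, where `x`
#' is a wildcard matching any residue. Each repeat is segmented into four
#' tetra-peptide motifs: the GYGS turn (positions 1-4), the TxTA strand
#' (5-8), the xxxS turn (9-12) and the xLxA strand (13-16). Three
#' consecutive repeats form a higher-order 48-residue block.
#'
#' @param pattern 16-character consensus string; `x` marks wildcard
#'   positions.
#' @param superperiod Number of 16-residue repeats per higher-order block.
#' @return An object of class `consensus_repeat`: a list with `pattern`,
#'   `motif_registers` (a tibble with one row per motif: name, role, start,
#'   end) and `superperiod`.
#' @export
#' @examples
#' consensus_repeat()
consensus_repeat <- function(pattern = "GYGSTxTAxxxSxLxA", superperiod = 3L) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (nchar(pattern) != 16) {
    stop("consensus pattern must be exactly 16 characters, got ", nchar(pattern))
  }
  if (!is.numeric(superperiod) || superperiod < 1) {
    stop("superperiod must be >= 1")
  }
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "x"))
  if (length(bad)) {
    stop("consensus contains non-standard characters: ", paste(bad, collapse = ", "))
  }
  registers <- tibble::tibble(
    name  = c("GYGS", "TxTA", "xxxS", "xLxA"),
    role  = c("turn", "strand", "turn", "strand"),
    start = c(1L, 5L, 9L, 13L),
    end   = c(4L, 8L, 12L, 16L)
  )
  structure(
    list(pattern = pattern, motif_registers = registers,
         superperiod = as.integer(superperiod)),
    class = "consensus_repeat"
  )
}

#' @export
print.consensus_repeat <- function(x, ...) {
  cat("<consensus_repeat> ", x$pattern, "\n", sep = "")
  cat("  motifs: ", paste(sprintf("%s[%d-%d,%s]", x$motif_registers$name,
                                  x$motif_registers$start, x$motif_registers$end,
                                  x$motif_registers$role), collapse = " "), "\n", sep = "")
  cat("  superperiod: ", x$superperiod, " repeats (", 16 * x$superperiod,
      " aa)\n", sep = "")
  invisible(x)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop("sequence must be a single character string")
  }
  if (nchar(sequence) == 0) stop("sequence is empty")
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("non-standard residue letter(s) in sequence: ",
         paste(sort(bad), collapse = ", "))
  }
  sequence
}

# identity of one 16-aa window against the consensus: wildcards excluded
# from numerator and denominator
window_identity <- function(window_chars, cons_chars) {
  informative <- cons_chars != "x"
  if (!any(informative)) return(NA_real_)
  sum(window_chars[informative] == cons_chars[informative]) / sum(informative)
}

#' Detect the tandem 16-residue repeat array of an INP sequence
#'
#' Scans all sixteen possible reading phases, scores each phase by the total
#' number of matched (non-wildcard) consensus positions over its windows,
#' and keeps the phase with the highest total (ties broken by the smallest
#' offset). Within the chosen phase the longest run of consecutive windows
#' with identity at or above `min_identity` is reported as the repeat array;
#' flanking leftovers shorter than a full repeat are reported with
#' `partial = TRUE` and are excluded from all downstream statistics.
#'
#' @param sequence Amino-acid sequence (single string, one-letter codes).
#' @param consensus A [consensus_repeat()] object.
#' @param min_identity Minimum per-repeat identity (fraction of matched
#'   non-wildcard positions) for a window to count as a repeat.
#' @param max_bridge Natural repeat arrays are contiguous, and single
#'   degenerate repeats occur inside otherwise clean arrays; up to this
#'   many consecutive sub-threshold windows are therefore retained when
#'   they are flanked by qualifying windows (set to 0 for strict
#'   thresholding).
#' @param sequence_id Identifier carried into the annotation.
#' @param numbering_start Residue number of the first sequence position
#'   (spans are reported in this numbering; default 1).
#' @return A `repeat_annotation`: a tibble with one row per repeat
#'   (`repeat_index`, `start`, `end`, `identity`, `partial`) and attributes
#'   `sequence`, `sequence_id`, `consensus` and `phase`.
#' @export
#' @examples
#' seq8 <- strrep("GYGSTQTAGEGSSLTA", 8)
#' detect_repeats(seq8)
detect_repeats <- function(sequence, consensus = consensus_repeat(),
                           min_identity = 0.5, max_bridge = 2L,
                           sequence_id = "seq", numbering_start = 1L) {
  sequence <- check_sequence(sequence)
  stopifnot(inherits(consensus, "consensus_repeat"))
  if (!is.numeric(min_identity) || min_identity < 0 || min_identity > 1) {
    stop("min_identity must be in [0, 1]")
  }
  chars <- strsplit(sequence, "")[[1]]
  cons <- strsplit(consensus$pattern, "")[[1]]
  nseq <- length(chars)
  informative <- cons != "x"

  # phase scoring: total matched informative positions across all windows
  phase_scores <- integer(16)
  for (off in 0:15) {
    starts <- seq.int(off + 1L, by = 16L, length.out = max(0L, (nseq - off) %/% 16L))
    score <- 0L
    for (s in starts) {
      w <- chars[s:(s + 15L)]
      score <- score + sum(w[informative] == cons[informative])
    }
    phase_scores[off + 1L] <- score
  }
  phase <- which.max(phase_scores) - 1L  # smallest offset wins ties

  starts <- seq.int(phase + 1L, by = 16L,
                    length.out = max(0L, (nseq - phase) %/% 16L))
  idents <- vapply(starts, function(s) {
    window_identity(chars[s:(s + 15L)], cons)
  }, numeric(1))

  ok <- idents >= min_identity
  # longest run of consecutive windows whose first and last qualify;
  # up to max_bridge consecutive sub-threshold windows are bridged when
  # flanked by qualifying ones (first run wins ties)
  pass_idx <- which(ok)
  best_len <- 0L; best_at <- 0L
  if (length(pass_idx)) {
    run_start <- pass_idx[1]; run_end <- pass_idx[1]
    commit <- function(s, e) {
      if (e - s + 1L > best_len) { best_len <<- e - s + 1L; best_at <<- s }
    }
    for (i in pass_idx[-1]) {
      if (i - run_end - 1L <= max_bridge) {
        run_end <- i
      } else {
        commit(run_start, run_end)
        run_start <- i; run_end <- i
      }
    }
    commit(run_start, run_end)
  }
  if (best_len == 0L) {
    rep_tbl <- tibble::tibble(repeat_index = integer(), start = integer(),
                              end = integer(), identity = numeric(),
                              partial = logical())
  } else {
    sel <- seq.int(best_at, best_at + best_len - 1L)
    rep_tbl <- tibble::tibble(
      repeat_index = seq_along(sel),
      start = as.integer(starts[sel]),
      end = as.integer(starts[sel] + 15L),
      identity = idents[sel],
      partial = FALSE
    )
    # flanking leftovers (partial repeats), reported but not analysed
    lead_len <- rep_tbl$start[1] - 1L
    if (lead_len > 0 && lead_len < 16) {
      rep_tbl <- dplyr::bind_rows(
        tibble::tibble(repeat_index = 0L, start = 1L,
                       end = lead_len, identity = NA_real_, partial = TRUE),
        rep_tbl
      )
    }
    tail_start <- rep_tbl$end[nrow(rep_tbl)] + 1L
    tail_len <- nseq - tail_start + 1L
    if (tail_len > 0 && tail_len < 16) {
      rep_tbl <- dplyr::bind_rows(
        rep_tbl,
        tibble::tibble(repeat_index = max(rep_tbl$repeat_index) + 1L,
                       start = tail_start, end = as.integer(nseq),
                       identity = NA_real_, partial = TRUE)
      )
    }
    rep_tbl$repeat_index <- seq_len(nrow(rep_tbl))
  }
  offset <- as.integer(numbering_start) - 1L
  rep_tbl$start <- rep_tbl$start + offset
  rep_tbl$end <- rep_tbl$end + offset
  new_repeat_annotation(rep_tbl, sequence = sequence, sequence_id = sequence_id,
                        consensus = consensus, phase = phase,
                        numbering_start = as.integer(numbering_start))
}

new_repeat_annotation <- function(tbl, sequence, sequence_id, consensus, phase,
                                  numbering_start = 1L) {
  structure(
    tbl,
    class = c("repeat_annotation", class(tibble::tibble())),
    sequence = sequence,
    sequence_id = sequence_id,
    consensus = consensus,
    phase = phase,
    numbering_start = numbering_start
  )
}

#' @export
print.repeat_annotation <- function(x, ...) {
  n_complete <- sum(!x$partial)
  cat("<repeat_annotation> ", attr(x, "sequence_id"), ": ", n_complete,
      " complete 16-aa repeat(s)",
      if (any(x$partial)) paste0(" + ", sum(x$partial), " partial"), "\n", sep = "")
  NextMethod()
}

# residue-string accessor for a repeat row (local sequence coordinates)
repeat_strings <- function(annotation) {
  seqc <- attr(annotation, "sequence")
  off <- attr(annotation, "numbering_start") - 1L
  substring(seqc, annotation$start - off, annotation$end - off)
}

#' Segment detected repeats into their four tetra-peptide motifs
#'
#' Each complete repeat is cut at the consensus registers into the GYGS
#' turn, TxTA strand, xxxS turn and xLxA strand. Partial repeats are kept
#' in the table but their motif columns are `NA`.
#'
#' @param annotation A `repeat_annotation` from [detect_repeats()].
#' @param consensus The consensus used for register boundaries; defaults to
#'   the one stored in `annotation`.
#' @return The annotation with four added character columns,
#'   `turn_gygs`, `strand_txta`, `turn_xxxs`, `strand_xlta`.
#' @export
segment_motifs <- function(annotation, consensus = NULL) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  if (nrow(annotation) == 0 || !any(!annotation$partial)) {
    stop("annotation has no complete repeat")
  }
  consensus <- consensus %||% attr(annotation, "consensus")
  reg <- consensus$motif_registers
  strs <- repeat_strings(annotation)
  cols <- list(
    turn_gygs   = substr(strs, reg$start[1], reg$end[1]),
    strand_txta = substr(strs, reg$start[2], reg$end[2]),
    turn_xxxs   = substr(strs, reg$start[3], reg$end[3]),
    strand_xlta = substr(strs, reg$start[4], reg$end[4])
  )
  out <- annotation
  for (nm in names(cols)) {
    v <- cols[[nm]]
    v[annotation$partial] <- NA_character_
    out[[nm]] <- v
  }
  out
}

#' Position-specific residue frequencies over the repeat array
#'
#' Counts residues at each of the 16 consensus positions over all complete
#' repeats, and derives motif-level conservation summaries (for example the
#' threonine frequency at the two solvent-exposed TxTA positions).
#'
#' @param annotation A `repeat_annotation` with at least one complete
#'   repeat.
#' @return A `position_frequency_table`: list with `counts` and
#'   `frequencies` (16 x 20 matrices, rows = consensus positions, columns =
#'   amino acids), `n_repeats`, and `motif_summary` (a tibble of named
#'   conservation statistics).
#' @export
position_frequencies <- function(annotation) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  complete <- annotation[!annotation$partial, , drop = FALSE]
  if (nrow(complete) == 0) stop("no complete repeats to tabulate")
  strs <- repeat_strings(annotation)[!annotation$partial]
  mat <- do.call(rbind, strsplit(strs, ""))
  counts <- matrix(0L, nrow = 16, ncol = 20,
                   dimnames = list(position = 1:16, residue = AA_ALPHABET))
  for (p in 1:16) {
    tb <- table(factor(mat[, p], levels = AA_ALPHABET))
    counts[p, ] <- as.integer(tb)
  }
  freqs <- counts / nrow(mat)
  ms <- tibble::tibble(
    statistic = c("thr_txta_pos1", "thr_txta_pos3", "ser_thr_xlta_pos1",
                  "tyr_gygs_pos2", "ser_gygs_pos4", "ser_xxxs_pos4",
                  "gln_txta_pos2"),
    register  = c(5L, 7L, 13L, 2L, 4L, 12L, 6L),
    frequency = c(freqs[5, "T"], freqs[7, "T"],
                  freqs[13, "S"] + freqs[13, "T"],
                  freqs[2, "Y"], freqs[4, "S"], freqs[12, "S"],
                  freqs[6, "Q"])
  )
  structure(
    list(counts = counts, frequencies = freqs, n_repeats = nrow(mat),
         motif_summary = ms),
    class = "position_frequency_table"
  )
}

#' @export
print.position_frequency_table <- function(x, ...) {
  cat("<position_frequency_table> over", x$n_repeats, "complete repeats\n")
  print(x$motif_summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.position_frequency_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, responseName = "count")) |>
    dplyr::mutate(
      position = as.integer(as.character(.data$position)),
      residue = as.character(.data$residue),
      frequency = .data$count / x$n_repeats
    )
}

#' @importFrom generics glance
#' @export
glance.position_frequency_table <- function(x, ...) {
  tibble::tibble(
    n_repeats = x$n_repeats,
    mean_top_frequency = mean(apply(x$frequencies, 1, max))
  )
}
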
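# Sliding-window probe candidate generation and the conjunctive
# specificity filter, with a naive in-package match oracle standing in
# for an external short-read aligner at desk scale.

#' Sliding 30-mer windows over contigs
#'
#' For a contig of length L >= `window`, windows start at 0, `step`,
#' 2 `step`, ... (0-based, half-open), giving
#' floor((L - window)/step) + 1 windows.  Windows containing N are
#' dropped and counted in the `n_dropped_n` attribute.
#'
#' @param contigs named character vector or `DNAStringSet` of
#'   sequences over A/C/G/T/N.
#' @param window window size in bp (default 30).
#' @param step step size in bp (default 15).
#' @return data frame with `candidate_id`, `contig_id`, `start`
#'   (0-based), `length`, `sequence`.
#' @export
sliding_windows <- function(contigs, window = 30, step = 15) {
  if (inherits(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (length(contigs) == 0) stopf("empty contig set")
  if (is.null(names(contigs))) stopf("contigs must be named")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stopf("sequences must be over A/C/G/T/N")
  rows <- lapply(names(contigs), function(id) {
    L <- nchar(contigs[[id]])
    if (L < window) return(NULL)
    starts <- seq(0, L - window, by = step)
    data.frame(contig_id = id, start = starts, length = window,
               sequence = substring(contigs[[id]], starts + 1,
                                    starts + window),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(contig_id = character(0),
                                      start = integer(0),
                                      length = integer(0),
                                      sequence = character(0))
  has_n <- grepl("N", out$sequence, fixed = TRUE)
  out <- out[!has_n, , drop = FALSE]
  out <- cbind(candidate_id = sprintf("%s:%d", out$contig_id, out$start),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_n") <- sum(has_n)
  out
}

#' Naive ungapped match oracle
#'
#' Scans every target (both strands) for ungapped occurrences of each
#' candidate with at most `max_mismatches` mismatches.  Exact hits get
#' evalue 0; mismatched hits get the documented monotone surrogate
#' evalue = number of mismatches.  Coverage is always 100 (full-length
#' ungapped alignment); identity = 100 (w - mm)/w.
#'
#' @param candidates data frame from [sliding_windows()] (columns
#'   `candidate_id`, `sequence`).
#' @param targets named character vector or `DNAStringSet`; names of
#'   the form `taxon|contig` attach a taxon label, otherwise the
#'   full name is the taxon.
#' @param max_mismatches maximum mismatches reported (<= 10).
#' @return data frame of hit records: `candidate_id`, `target_id`,
#'   `taxon`, `strand`, `evalue`, `coverage`, `identity`.
#' @export
naive_match_oracle <- function(candidates, targets, max_mismatches = 3) {
  if (max_mismatches > 10) stopf("max_mismatches must be <= 10")
  if (!inherits(targets, "DNAStringSet"))
    targets <- Biostrings::DNAStringSet(targets)
  if (length(targets) == 0 || nrow(candidates) == 0)
    return(data.frame(candidate_id = character(0), target_id = character(0),
                      taxon = character(0), strand = character(0),
                      evalue = numeric(0), coverage = numeric(0),
                      identity = numeric(0)))
  taxa <- sub("\\|.*$", "", names(targets))
  rows <- list()
  for (ci in seq_len(nrow(candidates))) {
    pat <- Biostrings::DNAString(candidates$sequence[ci])
    w <- length(pat)
    for (ti in seq_along(targets)) {
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(p, targets[[ti]],
                                      max.mismatch = max_mismatches)
        if (length(m) == 0) next
        hit_seq <- as.character(m)
        mm <- vapply(hit_seq, function(s) {
          sum(strsplit(s, "")[[1]] != strsplit(as.character(p), "")[[1]])
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          candidate_id = candidates$candidate_id[ci],
          target_id = names(targets)[ti],
          taxon = taxa[ti],
          strand = strand,
          evalue = unname(mm),
          coverage = 100,
          identity = 100 * (w - mm) / w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(candidate_id = character(0), target_id = character(0),
                      taxon = character(0), strand = character(0),
                      evalue = numeric(0), coverage = numeric(0),
                      identity = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specificity filter for probe candidates
#'
#' A candidate is removed when it has at least one off-target hit
#' satisfying ALL of: evalue < `evalue_max`, coverage >=
#' `coverage_min`, identity >= `identity_min` (conjunctive reading).
#' Hits whose `taxon` equals the candidate's own `self_taxon` are
#' ignored.
#'
#' @param candidates data frame with `candidate_id`.
#' @param hits hit-record data frame (see [naive_match_oracle()]).
#' @param self_taxon taxon/genus label of the candidates' source
#'   genome; hits to it are not disqualifying.
#' @param evalue_max,coverage_min,identity_min filter cutoffs
#'   (defaults 20, 60, 90).
#' @return the retained subset of `candidates`.
#' @export
specificity_filter <- function(candidates, hits, self_taxon = NULL,
                               evalue_max = 20, coverage_min = 60,
                               identity_min = 90) {
  if (nrow(hits) > 0) {
    assert_cols(hits, c("candidate_id", "taxon", "evalue", "coverage",
                        "identity"), "hit table")
    unknown <- setdiff(hits$candidate_id, candidates$candidate_id)
    if (length(unknown) > 0)
      stopf("hit(s) referencing unknown candidate: %s",
            paste(head(unknown, 5), collapse = ", "))
  }
  disq <- hits[hits$evalue < evalue_max & hits$coverage >= coverage_min &
                 hits$identity >= identity_min, , drop = FALSE]
  if (!is.null(self_taxon))
    disq <- disq[!disq$taxon %in% self_taxon, , drop = FALSE]
  out <- candidates[!candidates$candidate_id %in% disq$candidate_id, ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-genus uniqueness screen
#'
#' Runs the naive oracle against labeled reference genome sets and
#' removes any candidate with a qualifying match in a genus other than
#' the candidates' own.
#'
#' @param candidates data frame from [sliding_windows()].
#' @param references named character vector or `DNAStringSet`; names
#'   must carry genus labels (`genus|contig`).
#' @param self_genus the candidates' own genus label.
#' @param max_mismatches oracle mismatch bound (default 3, i.e. the
#'   90\% identity boundary for 30-mers).
#' @return retained subset of `candidates`.
#' @export
cross_set_uniqueness <- function(candidates, references, self_genus,
                                 max_mismatches = 3) {
  if (length(references) == 0) return(candidates)
  nm <- names(references)
  if (is.null(nm) || any(nm == "")) stopf("references must be labeled")
  hits <- naive_match_oracle(candidates, references, max_mismatches)
  specificity_filter(candidates, hits, self_taxon = self_genus)
}

#' Select the final probe set
#'
#' Ranks retained candidates by fewest near-miss hits, then by
#' coordinate, and greedily takes up to `k` mutually non-overlapping
#' windows (distinct genomic loci).  A shortfall below `k` is a
#' warning, not an error.
#'
#' @param retained data frame of retained candidates (columns
#'   `candidate_id`, `contig_id`, `start`, `length`).
#' @param k probe-set size (default 10).
#' @param near_miss optional named integer vector of near-miss hit
#'   counts per candidate id (default all 0).
#' @return object of class `probe_set`: the selected rows, ordered.
#' @export
select_probe_set <- function(retained, k = 10, near_miss = NULL) {
  if (nrow(retained) == 0) {
    warnf("no retained candidates; empty probe set")
    return(structure(retained, class = c("probe_set", class(retained))))
  }
  nm <- rep(0L, nrow(retained))
  if (!is.null(near_miss)) {
    idx <- match(retained$candidate_id, names(near_miss))
    nm <- ifelse(is.na(idx), 0L, near_miss[idx])
  }
  ord <- order(nm, retained$contig_id, retained$start)
  r <- retained[ord, , drop = FALSE]
  taken <- integer(0)
  for (i in seq_len(nrow(r))) {
    overlaps <- any(r$contig_id[taken] == r$contig_id[i] &
                      abs(r$start[taken] - r$start[i]) < r$length[i])
    if (!isTRUE(overlaps)) taken <- c(taken, i)
    if (length(taken) == k) break
  }
  if (length(taken) < k)
    warnf("only %d non-overlapping probes available (requested %d)",
          length(taken), k)
  out <- r[taken, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("probe_set", class(out)))
}

#' End-to-end probe pipeline on a target genome
#'
#' Windows the target, screens candidates against off-target genome
#' sets with the naive oracle plus specificity filter, and selects the
#' final probe set.
#'
#' @param target named character vector or `DNAStringSet` of target
#'   contigs.
#' @param offtargets labeled reference sequences (`genus|contig`
#'   names); may be empty.
#' @param self_genus genus label of the target (its own hits are
#'   ignored).
#' @param k probe-set size.
#' @param max_mismatches oracle mismatch bound.
#' @return list with `candidates`, `retained`, and `probes`.
#' @export
probe_pipeline <- function(target, offtargets, self_genus = "target",
                           k = 10, max_mismatches = 3) {
  cand <- sliding_windows(target)
  retained <- cross_set_uniqueness(cand, offtargets, self_genus,
                                   max_mismatches)
  probes <- select_probe_set(retained, k = k)
  list(candidates = cand, retained = retained, probes = probes)
}
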
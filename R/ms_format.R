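#' Parse ms-format simulator output
#'
#' Reads the text format of Hudson's `ms` (and compatible simulators such
#' as msprime's `mspms`): per-replicate blocks introduced by `//`, a
#' `segsites:` line, a `positions:` line and one 0/1 row per haplotype.
#' Rows are assigned to populations in listed order; within each
#' population the first `n_discovery` rows are the discovery panel and the
#' following `n_typing` rows the typing sample (recorded in the returned
#' objects' role labels).
#'
#' A trailing `seed=<int>` on a `//` line (as written by
#' [simulate_replicates()] and [write_ms()]) is picked up as the
#' replicate's seed. Tied positions (possible in genuine `ms` output,
#' which prints few decimals) are broken by a minimal upward nudge, with a
#' warning.
#'
#' @param text A file path, a single string, or a character vector of
#'   lines.
#' @param design A [sampling_design()] giving per-population discovery and
#'   typing counts, or `NULL` to label every haplotype `"typing"`.
#' @param pop_sizes Haplotype count per population in row order. Defaults
#'   to the design's `n_discovery + n_typing` (or `n_discovery` under
#'   reuse) for every population it can infer, else to a single
#'   population holding all rows.
#' @param n_pops_hint Number of populations when both `design` and
#'   `pop_sizes` leave it ambiguous.
#' @param length Region length in bp recorded on the datasets.
#' @return A list of [haplotype_dataset()] objects, `replicate_id` 0-based
#'   in block order.
#' @export
#' @examples
#' txt <- c("ms 4 1", "123", "", "//", "segsites: 2",
#'          "positions: 0.1 0.5", "01", "11", "00", "01")
#' parse_ms_output(txt, pop_sizes = c(2, 2))[[1]]
parse_ms_output <- function(text, design = NULL, pop_sizes = NULL,
                            n_pops_hint = NULL, length = 50000) {
  lines <- if (is.character(text) && length(text) == 1 &&
               !grepl("\n", text, fixed = TRUE) && file.exists(text)) {
    readLines(text)
  } else if (is.character(text) && length(text) == 1) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }

  starts <- grep("^//", lines)
  if (!length(starts)) abort("no replicate blocks ('//' lines) found.")

  if (is.null(pop_sizes) && !is.null(design) && !is.null(n_pops_hint)) {
    per_pop <- if (design$reuse_discovery_as_typing) design$n_discovery
               else design$n_discovery + design$n_typing
    pop_sizes <- rep(per_pop, n_pops_hint)
  }

  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[b]
    seed <- NA_integer_
    sm <- regmatches(lines[i], regexec("seed=([0-9]+)", lines[i]))[[1]]
    if (length(sm) == 2) seed <- as.integer(sm[2])

    if (i + 1 > ends[b] || !grepl("^segsites:", lines[i + 1])) {
      abort(sprintf("line %d: expected 'segsites:' after '//'.", i + 1))
    }
    S <- suppressWarnings(
      as.integer(sub("^segsites:\\s*", "", lines[i + 1])))
    if (is.na(S)) abort(sprintf("line %d: unparseable segsites count.", i + 1))

    if (S == 0L) {
      n_rows <- if (!is.null(pop_sizes)) sum(pop_sizes) else 0L
      mat <- matrix(integer(), nrow = n_rows, ncol = 0)
      positions <- numeric()
      row_lines <- integer()
    } else {
      if (i + 2 > ends[b] || !grepl("^positions:", lines[i + 2])) {
        abort(sprintf("line %d: expected 'positions:' line.", i + 2))
      }
      positions <- suppressWarnings(as.numeric(
        strsplit(trimws(sub("^positions:", "", lines[i + 2])),
                 "\\s+")[[1]]))
      if (anyNA(positions) || length(positions) != S) {
        abort(sprintf(
          "line %d: positions count (%d) does not match segsites (%d).",
          i + 2, length(positions), S))
      }
      body <- lines[seq.int(i + 3, ends[b])]
      keep <- nzchar(trimws(body))
      row_lines <- seq.int(i + 3, ends[b])[keep]
      rows <- body[keep]
      if (!is.null(pop_sizes)) {
        n_rows <- sum(pop_sizes)
        if (length(rows) < n_rows) {
          abort(sprintf(
            "replicate %d: %d haplotype rows found, %d expected.",
            b - 1, length(rows), n_rows))
        }
        rows <- rows[seq_len(n_rows)]
        row_lines <- row_lines[seq_len(n_rows)]
      }
      bad_len <- which(nchar(rows) != S)
      if (length(bad_len)) {
        abort(sprintf("line %d: row length %d does not match segsites %d.",
                      row_lines[bad_len[1]], nchar(rows[bad_len[1]]), S))
      }
      bad_chr <- which(!grepl("^[01]*$", rows))
      if (length(bad_chr)) {
        abort(sprintf("line %d: haplotype rows may only contain 0 and 1.",
                      row_lines[bad_chr[1]]))
      }
      mat <- matrix(as.integer(charToRaw(paste(rows, collapse = ""))) - 48L,
                    nrow = length(rows), ncol = S, byrow = TRUE)
      if (S > 1 && any(diff(positions) <= 0)) {
        warn("tied/non-increasing positions; breaking ties by a tiny nudge.")
        positions <- pmin(cummax(positions) + seq_along(positions) * 1e-12,
                          1 - 1e-12)
      }
    }

    sizes <- if (!is.null(pop_sizes)) pop_sizes else nrow(mat)
    pop <- rep(seq_along(sizes), sizes)
    role <- rep("typing", nrow(mat))
    reuse <- FALSE
    if (!is.null(design)) {
      reuse <- design$reuse_discovery_as_typing
      per_pop <- if (reuse) design$n_discovery
                 else design$n_discovery + design$n_typing
      if (any(sizes != per_pop)) {
        abort("`pop_sizes` do not match the sampling design.")
      }
      role <- unlist(lapply(sizes, function(n) {
        if (reuse) rep("discovery", n)
        else rep(c("discovery", "typing"),
                 c(design$n_discovery, design$n_typing))
      }))
    }
    out[[b]] <- haplotype_dataset(mat, positions, pop, role,
                                  replicate_id = b - 1L, seed = seed,
                                  length = length,
                                  reuse_discovery_as_typing = reuse)
  }
  out
}

#' Write replicates as ms-format text
#'
#' Inverse of [parse_ms_output()] up to the floating-point formatting of
#' positions (10 decimals).
#'
#' @param datasets A `haplotype_dataset` or list of them.
#' @param path Optional file path; when `NULL` the lines are returned only.
#' @param digits Decimal digits for positions.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_ms <- function(datasets, path = NULL, digits = 10) {
  if (inherits(datasets, "haplotype_dataset")) datasets <- list(datasets)
  n_sam <- if (length(datasets)) nrow(datasets[[1]]$haplotypes) else 0L
  lines <- c(sprintf("ascbias %d %d", n_sam, length(datasets)),
             sprintf("%d", if (length(datasets) &&
                               !is.na(datasets[[1]]$seed))
                             datasets[[1]]$seed else 0L))
  for (ds in datasets) {
    header <- if (is.na(ds$seed)) "//" else sprintf("// seed=%d", ds$seed)
    lines <- c(lines, "", header,
               sprintf("segsites: %d", ncol(ds$haplotypes)))
    if (ncol(ds$haplotypes)) {
      fmt <- paste0("%.", digits, "f")
      lines <- c(lines,
                 paste("positions:",
                       paste(sprintf(fmt, ds$positions), collapse = " ")),
                 apply(ds$haplotypes, 1, paste, collapse = ""))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
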
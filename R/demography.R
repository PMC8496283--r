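#' Coalescent simulation parameters
#'
#' Scaled parameters of one simulated region. `theta = 4*N0*mu*l` and
#' `rho = 4*N0*r*l` are the population mutation and recombination rates of
#' the whole region; the defaults (`theta = rho = 20` over 50 kb) correspond
#' to per-site rates of 1e-8 with a reference diploid deme size of
#' `N0 = 10^4`.
#'
#' @param theta Scaled region mutation rate, `> 0`.
#' @param rho Scaled region recombination rate, `>= 0`.
#' @param length Region length in bp, `>= 1`.
#' @param N0 Reference diploid deme size, `>= 2`. Sets the time scale
#'   (`4*N0` generations) in which event times are expressed.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' sim_params()
sim_params <- function(theta = 20, rho = 20, length = 50000, N0 = 10000) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    abort("`theta` must be a single positive number.")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0) {
    abort("`rho` must be a single non-negative number.")
  }
  if (!is.numeric(length) || length < 1) {
    abort("`length` must be >= 1.")
  }
  if (!is.numeric(N0) || N0 < 2) {
    abort("`N0` must be >= 2.")
  }
  structure(list(theta = theta, rho = rho, length = as.integer(length),
                 N0 = N0),
            class = "sim_params")
}

#' Discovery/typing sampling design
#'
#' How many haplotypes per population go into the SNP discovery panel and
#' into the typing sample. By default the two sets are disjoint: the
#' simulator draws `n_discovery + n_typing` haplotypes per deme and labels
#' the first `n_discovery` as the discovery panel. With
#' `reuse_discovery_as_typing = TRUE` only `n_discovery` haplotypes are
#' drawn and the discovery panel itself is genotyped, the design under
#' which ascertainment truncation is sharpest.
#'
#' @param n_discovery Haplotypes per population in the discovery panel
#'   (`>= 2`).
#' @param n_typing Haplotypes per population in the typing sample (`>= 2`).
#' @param reuse_discovery_as_typing Type the discovery haplotypes
#'   themselves instead of a disjoint sample?
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(n_discovery = 100, n_typing = 100,
                            reuse_discovery_as_typing = FALSE) {
  if (!is.numeric(n_discovery) || n_discovery < 2) {
    abort("`n_discovery` must be >= 2.")
  }
  if (!is.numeric(n_typing) || n_typing < 2) {
    abort("`n_typing` must be >= 2.")
  }
  structure(list(n_discovery = as.integer(n_discovery),
                 n_typing = as.integer(n_typing),
                 reuse_discovery_as_typing =
                   isTRUE(reuse_discovery_as_typing)),
            class = "sampling_design")
}

new_demography <- function(deme_sizes, migration_matrix, events, name) {
  structure(list(deme_sizes = deme_sizes,
                 migration_matrix = migration_matrix,
                 events = events,
                 name = name),
            class = "demography")
}

empty_events <- function() {
  tibble(time = double(), kind = character(), pop = integer(),
         source = integer(), dest = integer(), size = double())
}

#' Generic demographic model description
#'
#' A demography is a set of constant-size demes, a matrix of scaled
#' migration rates, and a time-ordered list of backward-in-time events.
#' Usually built through [island_model()], [stepping_stone_model()] or
#' [split_model()]; this constructor is for custom histories and for
#' reading configurations back from disk.
#'
#' @param deme_sizes Diploid size of each deme.
#' @param migration_matrix Square matrix of scaled migration rates in
#'   `4*N0*m` units, zero diagonal; entry `(i, j)` is the rate at which
#'   deme `i` receives migrants from deme `j`.
#' @param events Tibble of events with columns `time` (in `4*N0`
#'   generations, strictly positive, sorted ascending), `kind`
#'   (`"split"` or `"size_change"`), `pop`, `source`, `dest`, `size`
#'   (diploid). Irrelevant columns are `NA`.
#' @param name Model label carried through outputs.
#' @return An object of class `demography`.
#' @export
demography <- function(deme_sizes, migration_matrix,
                       events = empty_events(), name = "custom") {
  x <- new_demography(as.numeric(deme_sizes), migration_matrix,
                      as_tibble(events), name)
  validate_demography(x)
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("<demography: %s> %d deme(s)\n", x$name, n_pops(x)))
  cat("deme sizes:", paste(format(x$deme_sizes), collapse = ", "), "\n")
  cat("migration matrix (4*N0*m):\n")
  print(x$migration_matrix)
  if (nrow(x$events)) {
    cat("events (time in 4*N0 generations):\n")
    print(as.data.frame(x$events))
  }
  invisible(x)
}

#' Number of demes in an object
#'
#' @param x A `demography`, `haplotype_dataset` or `typing_data` object.
#' @return Integer number of demes/populations.
#' @export
n_pops <- function(x) UseMethod("n_pops")

#' @export
n_pops.demography <- function(x) length(x$deme_sizes)

validate_demography <- function(x) {
  m <- x$migration_matrix
  k <- length(x$deme_sizes)
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
    abort("`migration_matrix` must be square with dimension = number of demes.")
  }
  if (any(m < 0)) abort("migration rates must be non-negative.")
  if (any(diag(m) != 0)) abort("`migration_matrix` must have a zero diagonal.")
  if (any(x$deme_sizes < 2)) abort("deme sizes must be >= 2.")
  ev <- x$events
  if (nrow(ev)) {
    if (any(ev$time <= 0)) abort("event times must be strictly positive.")
    if (is.unsorted(ev$time)) abort("events must be sorted ascending in time.")
    bad <- !ev$kind %in% c("split", "size_change")
    if (any(bad)) abort("event kinds must be 'split' or 'size_change'.")
  }
  x
}

#' Symmetric island model
#'
#' `n_pops` demes of constant equal size exchanging migrants symmetrically.
#' Under the default `"total"` convention (the `-I` convention of the ms
#' simulator, with which the study's migration rates are stated),
#' `scaled_migration = 4*N0*m` is the total scaled immigration rate into
#' each deme, divided equally among the other demes; under `"pairwise"` it
#' is the rate of each ordered deme pair. The two coincide for two demes.
#'
#' @param n_pops Number of demes, `>= 2`.
#' @param scaled_migration Scaled migration rate `4*N0*m`, `>= 0`.
#' @param convention `"total"` (ms `-I`) or `"pairwise"`.
#' @param N0 Diploid size of every deme.
#' @return A [demography()] object.
#' @export
#' @examples
#' island_model(2, 0.1)
#' island_model(3, 0.3)$migration_matrix  # each off-diagonal = 0.15
island_model <- function(n_pops = 2, scaled_migration = 0.1,
                         convention = c("total", "pairwise"),
                         N0 = 10000) {
  convention <- match.arg(convention)
  if (n_pops < 2) abort("island model needs `n_pops` >= 2.")
  if (scaled_migration < 0) abort("`scaled_migration` must be >= 0.")
  rate <- if (convention == "total") {
    scaled_migration / (n_pops - 1)
  } else {
    scaled_migration
  }
  m <- matrix(rate, n_pops, n_pops)
  diag(m) <- 0
  demography(rep(N0, n_pops), m,
             name = sprintf("island_%dpop_4Nm%g", n_pops, scaled_migration))
}

#' One-dimensional stepping-stone model
#'
#' Demes arranged on a line; migration occurs only between adjacent demes,
#' at scaled rate `scaled_migration_adjacent = 4*N0*m` per ordered adjacent
#' pair.
#'
#' @param n_pops Number of demes, `>= 3`.
#' @param scaled_migration_adjacent Scaled migration rate between adjacent
#'   demes, `>= 0`.
#' @param N0 Diploid size of every deme.
#' @return A [demography()] object.
#' @export
#' @examples
#' stepping_stone_model(3, 0.3)$migration_matrix
stepping_stone_model <- function(n_pops = 3, scaled_migration_adjacent = 0.3,
                                 N0 = 10000) {
  if (n_pops < 3) abort("stepping-stone model needs `n_pops` >= 3.")
  if (scaled_migration_adjacent < 0) {
    abort("`scaled_migration_adjacent` must be >= 0.")
  }
  m <- matrix(0, n_pops, n_pops)
  for (i in seq_len(n_pops - 1)) {
    m[i, i + 1] <- scaled_migration_adjacent
    m[i + 1, i] <- scaled_migration_adjacent
  }
  demography(rep(N0, n_pops), m,
             name = sprintf("stepping_stone_%dpop_4Nm%g", n_pops,
                            scaled_migration_adjacent))
}

#' Serial population-split model
#'
#' Three populations without migration. Population II is founded from
#' population I at time `t1` (in `4*N0` generations before present) and
#' population III from population II at `t2 < t1`. Each founding passes
#' through a one-generation founder bottleneck at size `f*N0` before the
#' deme grows to `N0`; backwards in time this is a size change of duration
#' `1/(4*N0)` scaled units immediately before the merge. The bottleneck's
#' coalescent effect is tiny at the default parameters but is modelled
#' literally; `f = 1` gives a clean split with no bottleneck.
#'
#' @param f1 Founder fraction of population II, in `(0, 1]`.
#' @param f2 Founder fraction of population III, in `(0, 1]`.
#' @param t1 Split time of II from I, in `4*N0` generations.
#' @param t2 Split time of III from II; must satisfy `t1 > t2 > 0`.
#' @param params [sim_params()] supplying `N0` (anchors the one-generation
#'   bottleneck duration).
#' @return A [demography()] object.
#' @export
#' @examples
#' split_model()  # f1 = 0.2, f2 = 0.1, t1 = 0.3, t2 = 0.2
split_model <- function(f1 = 0.2, f2 = 0.1, t1 = 0.3, t2 = 0.2,
                        params = sim_params()) {
  if (!(t1 > t2 && t2 > 0)) abort("need `t1` > `t2` > 0.")
  if (!(f1 > 0 && f1 <= 1 && f2 > 0 && f2 <= 1)) {
    abort("founder fractions must lie in (0, 1].")
  }
  N0 <- params$N0
  gen <- 1 / (4 * N0)  # one generation in 4*N0-scaled time
  ev <- list()
  if (f2 < 1) {
    ev <- c(ev, list(tibble(time = t2 - gen, kind = "size_change",
                            pop = 3L, source = NA_integer_,
                            dest = NA_integer_, size = f2 * N0)))
  }
  ev <- c(ev, list(tibble(time = t2, kind = "split", pop = NA_integer_,
                          source = 3L, dest = 2L, size = NA_real_)))
  if (f1 < 1) {
    ev <- c(ev, list(tibble(time = t1 - gen, kind = "size_change",
                            pop = 2L, source = NA_integer_,
                            dest = NA_integer_, size = f1 * N0)))
  }
  ev <- c(ev, list(tibble(time = t1, kind = "split", pop = NA_integer_,
                          source = 2L, dest = 1L, size = NA_real_)))
  events <- dplyr::bind_rows(ev)
  demography(rep(N0, 3), matrix(0, 3, 3), events,
             name = sprintf("split_f1%g_f2%g_t1%g_t2%g", f1, f2, t1, t2))
}

#' Single panmictic deme
#'
#' Convenience constructor for calibration runs (e.g. checking `E[pi] =
#' theta` against neutral theory).
#'
#' @param N0 Diploid deme size.
#' @return A [demography()] object.
#' @export
panmictic_model <- function(N0 = 10000) {
  demography(N0, matrix(0, 1, 1), name = "panmictic")
}

#' Write or read a demography configuration
#'
#' Serializes a [demography()] (plus optional simulation parameters and
#' sampling design) to a YAML file and reads it back; the round trip
#' reproduces the object exactly.
#'
#' @param x A `demography` object.
#' @param path File path.
#' @param params Optional [sim_params()] to store alongside.
#' @param design Optional [sampling_design()] to store alongside.
#' @return `write_demography_config()` returns `path` invisibly;
#'   `read_demography_config()` returns a list with elements `demography`
#'   and, when present in the file, `params` and `design`.
#' @export
write_demography_config <- function(x, path, params = NULL, design = NULL) {
  stopifnot(inherits(x, "demography"))
  cfg <- list(demography = list(
    name = x$name,
    deme_sizes = x$deme_sizes,
    migration_matrix = apply(x$migration_matrix, 1, as.list,
                             simplify = FALSE),
    events = if (nrow(x$events)) {
      lapply(seq_len(nrow(x$events)), function(i) {
        row <- as.list(x$events[i, ])
        row[!vapply(row, is.na, logical(1))]
      })
    }
  ))
  if (!is.null(params)) cfg$params <- unclass(params)
  if (!is.null(design)) cfg$design <- unclass(design)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_demography_config
#' @export
read_demography_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- cfg$demography
  k <- length(d$deme_sizes)
  m <- matrix(unlist(d$migration_matrix), nrow = k, byrow = TRUE)
  events <- if (length(d$events)) {
    dplyr::bind_rows(lapply(d$events, function(ev) {
      tibble(time = ev$time, kind = ev$kind,
             pop = if (is.null(ev$pop)) NA_integer_ else as.integer(ev$pop),
             source = if (is.null(ev$source)) NA_integer_
                      else as.integer(ev$source),
             dest = if (is.null(ev$dest)) NA_integer_
                    else as.integer(ev$dest),
             size = if (is.null(ev$size)) NA_real_ else ev$size)
    }))
  } else {
    empty_events()
  }
  out <- list(demography = demography(unlist(d$deme_sizes), m, events,
                                      name = d$name))
  if (!is.null(cfg$params)) out$params <- do.call(sim_params, cfg$params)
  if (!is.null(cfg$design)) out$design <- do.call(sampling_design, cfg$design)
  out
}
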
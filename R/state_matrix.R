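#' Construct a validated state matrix
#'
#' A state matrix `C` encodes the activity of `n` input neurons across `m`
#' distinct input states: entry `C[k, l]` is the (non-negative) activity
#' effectiveness of neuron `l` during state `k`, typically a spike count.
#' Rows index states, columns index neurons.  Entries are stored as doubles
#' so that real-valued effectiveness measures are supported alongside
#' integer spike counts.
#'
#' @param x A numeric matrix (or object coercible to one) with `m >= 1` rows
#'   and `n >= 1` columns, all entries finite and `>= 0`.
#' @return An object of class `state_matrix` (a numeric matrix).
#' @examples
#' C <- state_matrix(rbind(c(1, 3, 1, 2), c(1, 2, 0, 1)))
#' @export
state_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  validate_state_matrix(x)
  class(x) <- c("state_matrix", class(x))
  x
}

#' Validate state-matrix invariants
#'
#' Checks that a matrix has at least one row and column and that every entry
#' is finite and non-negative; stops with the position of the first
#' offending entry otherwise.
#'
#' @param x A numeric matrix.
#' @return Invisibly, `x`.
#' @export
validate_state_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("state matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("state matrix must have at least 1 row and 1 column", call. = FALSE)
  }
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    ij <- arrayInd(which(bad)[1L], dim(x))
    stop(sprintf(
      "state matrix entry (%d,%d) is %s; entries must be finite and >= 0",
      ij[1L], ij[2L], format(x[ij[1L], ij[2L]])
    ), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("state matrix: %d states (rows) x %d neurons (columns)\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a state matrix from delimited text
#'
#' Reads a plain-text matrix file, one input state per row, fields separated
#' by commas and/or whitespace.  Validation is applied on read; ragged rows,
#' non-numeric tokens and negative entries are reported with their position.
#'
#' @param path Path to the text file.
#' @param transpose If `TRUE` the file stores neurons in rows and states in
#'   columns and is transposed after reading.
#' @param header If `TRUE` the first non-blank line is discarded.
#' @return A [state_matrix()].
#' @export
read_state_matrix <- function(path, transpose = FALSE, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  toks <- strsplit(lines, "[,;[:space:]]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  ncols <- lengths(toks)
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    stop(sprintf("row %d has %d values, expected %d", bad, ncols[bad],
                 ncols[1L]), call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1L]
      stop(sprintf("non-numeric token '%s' at entry (%d,%d)",
                   toks[[i]][j], i, j), call. = FALSE)
    }
    neg <- vals[[i]] < 0
    if (any(neg)) {
      j <- which(neg)[1L]
      stop(sprintf("negative entry (%d,%d): %s", i, j,
                   format(vals[[i]][j])), call. = FALSE)
    }
  }
  x <- do.call(rbind, vals)
  if (transpose) x <- t(x)
  state_matrix(x)
}

#' Write a state matrix to delimited text
#'
#' Entries are formatted with 17 significant digits so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param x A [state_matrix()] or numeric matrix.
#' @param path Output file path.
#' @param sep Field separator (default single space).
#' @return Invisibly, `path`.
#' @export
write_state_matrix <- function(x, path, sep = " ") {
  validate_state_matrix(as.matrix(unclass(x)))
  lines <- apply(unclass(x), 1L, function(row) {
    paste(vapply(row, function(v) formatC(v, digits = 17, format = "g"),
                 character(1)), collapse = sep)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated spike-train set
#'
#' A spike-train set holds spike events `(neuron index, spike time)` for a
#' recording divided into `num_slots` consecutive time slots of duration
#' `slot_duration` seconds; each slot presents one input state.
#'
#' @param neuron Integer vector of neuron indices in `1..num_neurons`.
#' @param time Numeric vector of spike times in seconds,
#'   `0 <= time < num_slots * slot_duration`.
#' @param slot_duration Slot duration `t_s` in seconds (positive).
#' @param num_slots Number of time slots (= number of input states).
#' @param num_neurons Number of input neurons.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(neuron, time, slot_duration, num_slots,
                            num_neurons) {
  neuron <- as.integer(neuron)
  time <- as.numeric(time)
  if (length(neuron) != length(time)) {
    stop("'neuron' and 'time' must have the same length", call. = FALSE)
  }
  stopifnot(slot_duration > 0, num_slots >= 1, num_neurons >= 1)
  t_max <- num_slots * slot_duration
  bad_n <- is.na(neuron) | neuron < 1L | neuron > num_neurons
  if (any(bad_n)) {
    i <- which(bad_n)[1L]
    stop(sprintf(
      "event %d (neuron %s, time %s): neuron index outside 1..%d",
      i, neuron[i], format(time[i]), num_neurons), call. = FALSE)
  }
  bad_t <- !is.finite(time) | time < 0 | time >= t_max
  if (any(bad_t)) {
    i <- which(bad_t)[1L]
    stop(sprintf(
      "event %d (neuron %d, time %s): spike time outside [0, %s)",
      i, neuron[i], format(time[i]), format(t_max)), call. = FALSE)
  }
  structure(
    list(neuron = neuron, time = time, slot_duration = slot_duration,
         num_slots = as.integer(num_slots),
         num_neurons = as.integer(num_neurons)),
    class = "spike_train_set"
  )
}

#' Read spike trains from two-column delimited text
#'
#' Each line holds `neuron_index time_seconds`, separated by commas and/or
#' whitespace.
#'
#' @inheritParams spike_train_set
#' @param path Path to the text file.
#' @return A [spike_train_set()].
#' @export
read_spike_trains <- function(path, slot_duration, num_slots, num_neurons) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(spike_train_set(integer(0), numeric(0), slot_duration, num_slots,
                           num_neurons))
  }
  toks <- strsplit(lines, "[,;[:space:]]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (any(lengths(toks) != 2L)) {
    bad <- which(lengths(toks) != 2L)[1L]
    stop(sprintf("spike file row %d does not have 2 fields", bad),
         call. = FALSE)
  }
  tab <- do.call(rbind, lapply(toks, as.numeric))
  spike_train_set(tab[, 1L], tab[, 2L], slot_duration, num_slots,
                  num_neurons)
}

#' Bin spike trains into a state matrix
#'
#' Counts the spikes of each neuron within each time slot.  Slots are
#' half-open intervals `[(k-1) t_s, k t_s)`, so a spike exactly on a slot
#' boundary is assigned to the later slot.  The resulting matrix has one row
#' per slot (input state) and one column per neuron.
#'
#' @param spikes A [spike_train_set()].
#' @return A [state_matrix()] of dimension `num_slots x num_neurons`.
#' @examples
#' s <- spike_train_set(c(1, 1, 2), c(0.1, 0.2, 1.5),
#'                      slot_duration = 1, num_slots = 2, num_neurons = 2)
#' bin_spike_trains(s)   # rbind(c(2, 0), c(0, 1))
#' @export
bin_spike_trains <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  m <- spikes$num_slots
  n <- spikes$num_neurons
  slot <- floor(spikes$time / spikes$slot_duration) + 1L
  idx <- (spikes$neuron - 1L) * m + slot
  counts <- tabulate(idx, nbins = m * n)
  state_matrix(matrix(counts, nrow = m, ncol = n))
}
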
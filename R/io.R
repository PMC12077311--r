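#' Write / read a trajectory as self-describing TSV
#'
#' Schema: `#`-prefixed metadata lines (seed, t_end, initial state and
#' count, generating parameters as JSON), a header line, then columns
#' `time`, `state`, `count`, `event_kind`. Times are written at full
#' double precision so write-then-read is the identity.
#'
#' @param traj a `"trajectory"`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a `"trajectory"`.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    sprintf("# seed: %s", if (is.null(traj$seed)) "unknown" else traj$seed),
    sprintf("# t_end: %.17g", traj$t_end),
    sprintf("# initial_state: %d", traj$initial_state),
    sprintf("# initial_count: %d", traj$initial_count),
    sprintf("# params: %s",
            jsonlite::toJSON(unclass(traj$params), auto_unbox = TRUE,
                             digits = NA)))
  writeLines(meta, con)
  writeLines("time\tstate\tcount\tevent_kind", con)
  if (length(traj$times))
    writeLines(sprintf("%.17g\t%d\t%d\t%s", traj$times, traj$states,
                       traj$counts, as.character(traj$event_kinds)), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta_sel <- startsWith(lines, "#")
  meta <- lines[meta_sel]
  body <- lines[!meta_sel]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^# %s:\\s*", key), "", hit[1])
  }
  if (!length(body) || body[1] != "time\tstate\tcount\tevent_kind")
    stop("parse error: missing or malformed header line")
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad))
    stop("parse error at line ", which(!meta_sel)[bad[1] + 1],
         ": expected 4 tab-separated fields")
  m <- if (length(fields)) matrix(unlist(fields), ncol = 4, byrow = TRUE)
       else matrix(character(0), ncol = 4)
  times <- as.numeric(m[, 1])
  states <- as.integer(m[, 2])
  counts <- as.integer(m[, 3])
  kinds <- m[, 4]
  if (any(is.na(times)) || any(is.na(states)) || any(is.na(counts)))
    stop("parse error: non-numeric time/state/count field")
  if (!all(kinds %in% c("synthesis", "removal", "switch")))
    stop("parse error: unknown event_kind")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("validation error: event times must be strictly increasing")
  seed_chr <- get_meta("seed")
  if (is.null(seed_chr) || identical(seed_chr, "unknown")) {
    if (is.null(seed_chr))
      warning("no seed metadata line; seed recorded as unknown")
    seed <- NA_integer_
  } else seed <- as.integer(seed_chr)
  t_end <- as.numeric(get_meta("t_end"))
  if (!length(t_end) || is.na(t_end))
    t_end <- if (length(times)) times[length(times)] else 0
  params_chr <- get_meta("params")
  params <- if (is.null(params_chr)) NULL else jsonlite::fromJSON(params_chr)
  new_trajectory(list(times = times, states = states, counts = counts,
                      kinds = match(kinds,
                                    c("synthesis", "removal", "switch"))),
                 seed = seed, t_end = t_end,
                 initial_state = as.integer(get_meta("initial_state") %||% 0),
                 initial_count = as.integer(get_meta("initial_count") %||% 0),
                 params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a copy-number pmf as TSV
#'
#' Columns `n`, `probability` at full precision, with the tail mass on
#' a `#` metadata line. Reading validates non-negativity and total
#' mass.
#'
#' @param pmf a [copy_number_pmf()].
#' @param path file path.
#' @export
write_pmf <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tail_mass: %.17g", pmf$tail_mass), con)
  writeLines("n\tprobability", con)
  writeLines(sprintf("%d\t%.17g", pmf$n, pmf$probs), con)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  tail_mass <- 0
  hit <- grep("^# tail_mass:", meta, value = TRUE)
  if (length(hit)) tail_mass <- as.numeric(sub("^# tail_mass:\\s*", "", hit[1]))
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("n", "probability") %in% names(df)))
    stop("parse error: pmf file needs columns n and probability")
  if (any(df$probability < 0))
    stop("validation error: negative probabilities")
  if (abs(sum(df$probability) + tail_mass - 1) > 1e-6)
    stop("validation error: probabilities plus tail mass must sum to 1")
  probs <- numeric(max(df$n) + 1)
  probs[df$n + 1] <- df$probability
  copy_number_pmf(probs, tail_mass)
}

#' Write / read a fluorescence trace as CSV
#'
#' Columns `time`, `intensity` at full precision. Reading validates
#' strictly increasing times and non-negative intensities.
#'
#' @param trace a [fluorescence_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = sprintf("%.17g", trace$times),
                   intensity = sprintf("%.17g", trace$intensities))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "intensity") %in% names(df)))
    stop("parse error: trace file needs columns time and intensity")
  fluorescence_trace(df$time, df$intensity)
}
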
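#' Build a pseudo-randomised fNMES trial design
#'
#' Constructs the per-subject trial list of the categorisation experiment:
#' 16 face identities each shown neutral (6 repetitions), happy (4) and sad
#' (4) in each of three stimulation conditions (off, early, late), plus 50
#' stimulation-only trials without a face -- 722 trials per subject
#' (288 neutral, 192 happy, 192 sad, 50 stimulation-only) drawn from a
#' 48-image stimulus pool (16 identities x 3 expressions).
#'
#' Presentation order is pseudo-random: no more than four consecutive trials
#' share an fNMES level and no more than four share an emotion level. Order
#' is found by shuffling followed by bounded local repair (violating trials
#' are swapped to random positions); if the constraints cannot be satisfied
#' within \code{maxIter} repairs the function stops rather than silently
#' relaxing them.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed integer master seed; the result is deterministic given it.
#' @param orderConstraints if \code{FALSE}, skip the run-length
#'   pseudo-randomisation (useful for choice/power simulations where
#'   presentation order is irrelevant); trial counts are unaffected.
#' @param maxIter repair-iteration bound per subject before erroring.
#' @return \code{data.frame} with columns \code{subject},
#'   \code{trial_index}, \code{identity} (1-16, NA on stimulation-only
#'   trials), \code{emotion} (neutral / happy / sad / none), \code{fnmes}
#'   (off / early / late / stim_only) and \code{repetition}.
#' @examples
#' d <- buildTrialDesign(1, seed = 1)
#' nrow(d)               # 722
#' table(d$emotion)
#' @seealso \code{\link{checkDesignConstraints}}
#' @export
buildTrialDesign <- function(nSubjects, seed, orderConstraints = TRUE,
                             maxIter = 20000L) {
  stopifnot(nSubjects >= 1)
  out <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    set.seed(deriveSeed(seed, paste0("design", s)))
    base <- subjectTrialPool()
    ord <- sample.int(nrow(base))
    if (orderConstraints)
      ord <- repairRunLengths(base, ord, maxRun = 4L, maxIter = maxIter)
    d <- base[ord, , drop = FALSE]
    d <- cbind(subject = s, trial_index = seq_len(nrow(d)), d)
    rownames(d) <- NULL
    out[[s]] <- d
  }
  do.call(rbind, out)
}

# The unordered 722-trial pool of one subject.
subjectTrialPool <- function() {
  cells <- expand.grid(identity = 1:16,
                       emotion = c("neutral", "happy", "sad"),
                       fnmes = c("off", "early", "late"),
                       stringsAsFactors = FALSE)
  reps <- ifelse(cells$emotion == "neutral", 6L, 4L)
  face <- cells[rep(seq_len(nrow(cells)), reps), , drop = FALSE]
  face$repetition <- unlist(lapply(reps, seq_len))
  stim <- data.frame(identity = NA_integer_, emotion = "none",
                     fnmes = "stim_only", repetition = seq_len(50L))
  rbind(face, stim)
}

# Repair a permutation until no 5-run of equal fnmes or emotion remains.
repairRunLengths <- function(base, ord, maxRun, maxIter) {
  n <- length(ord)
  iter <- 0L
  repeat {
    fn <- base$fnmes[ord]
    em <- base$emotion[ord]
    bad <- firstRunViolation(fn, maxRun)
    if (is.na(bad)) bad <- firstRunViolation(em, maxRun)
    if (is.na(bad)) return(ord)
    iter <- iter + 1L
    if (iter > maxIter)
      stop("could not satisfy run-length constraints after ", maxIter,
           " repairs; refusing to relax them")
    j <- sample.int(n, 1L)
    tmp <- ord[bad]; ord[bad] <- ord[j]; ord[j] <- tmp
  }
}

# Index of the last element of the first run longer than maxRun, else NA.
firstRunViolation <- function(x, maxRun) {
  r <- rle(x)
  k <- which(r$lengths > maxRun)
  if (!length(k)) return(NA_integer_)
  sum(r$lengths[seq_len(k[1] - 1)]) + maxRun + 1L
}

#' Check pseudo-randomisation constraints of a trial design
#'
#' Scans every window of five consecutive trials within each subject and
#' reports windows in which all five share the same fNMES level or the same
#' emotion level.
#'
#' @param design a design \code{data.frame} as produced by
#'   \code{\link{buildTrialDesign}}.
#' @return \code{data.frame} with columns \code{subject}, \code{field}
#'   (\code{"fnmes"} or \code{"emotion"}), \code{start} (first trial index
#'   of the offending window) and \code{level}; zero rows iff both
#'   constraints hold.
#' @examples
#' d <- buildTrialDesign(1, seed = 7)
#' nrow(checkDesignConstraints(d))   # 0
#' @export
checkDesignConstraints <- function(design) {
  out <- list()
  for (s in unique(design$subject)) {
    d <- design[design$subject == s, , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    for (field in c("fnmes", "emotion")) {
      x <- d[[field]]
      n <- length(x)
      if (n < 5L) next
      for (i in seq_len(n - 4L)) {     # brute-force length-5 window scan
        w <- x[i:(i + 4L)]
        if (length(unique(w)) == 1L)
          out[[length(out) + 1L]] <- data.frame(
            subject = s, field = field, start = d$trial_index[i],
            level = w[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(subject = integer(0), field = character(0),
                      start = integer(0), level = character(0)))
  do.call(rbind, out)
}
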
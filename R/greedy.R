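#' Greedy running-mean ppm clustering
#'
#' Core clustering primitive shared by mass-trace consolidation (across scans
#' of one infusion) and cross-file peak alignment. Peaks must already be
#' sorted ascending by m/z (ties broken by the caller). The scan moves left to
#' right: a peak joins the currently open cluster iff its m/z deviates from
#' the running mean of the cluster's members by at most `ppm_tol` parts per
#' million; otherwise the cluster is closed and a new one opened. The mean is
#' updated after every admission.
#'
#' @param mz numeric vector of m/z values, sorted ascending.
#' @param ppm_tol positive ppm tolerance (deviation measured against the
#'   running mean, not the first member).
#' @return integer vector of cluster ids (1-based, contiguous, non-decreasing).
#' @keywords internal
greedy_ppm_cluster <- function(mz, ppm_tol) {
  stopifnot(is.numeric(mz), ppm_tol > 0)
  n <- length(mz)
  if (n == 0L) return(integer(0))
  if (is.unsorted(mz)) stop("greedy_ppm_cluster: mz must be sorted ascending")
  cl <- integer(n)
  cl[1L] <- 1L
  cur <- 1L
  run_sum <- mz[1L]
  run_n <- 1L
  for (i in seq_len(n)[-1L]) {
    m <- run_sum / run_n
    if (abs(mz[i] - m) / m * 1e6 <= ppm_tol) {
      run_sum <- run_sum + mz[i]
      run_n <- run_n + 1L
    } else {
      cur <- cur + 1L
      run_sum <- mz[i]
      run_n <- 1L
    }
    cl[i] <- cur
  }
  cl
}
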
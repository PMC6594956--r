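#' ChIP-rx spike-in normalization factor
#'
#' Input-corrected spike ratio: the spike fraction of the input sample divided
#' by the spike fraction of the IP sample,
#' \deqn{f = \frac{n_{spike,input}/n_{target,input}}{n_{spike,IP}/n_{target,IP}}.}
#' A global loss of target-genome IP material inflates the spike share of the
#' IP library and drives the factor below 1, so multiplying a
#' tags-per-10-million track by `f` restores between-condition
#' quantitativeness.
#'
#' @param n_target_ip mapped target-genome (e.g. hg19) reads in the IP library
#' @param n_spike_ip mapped spike-genome (e.g. dm3) reads in the IP library
#' @param n_target_input,n_spike_input same for the input library
#' @return positive scalar factor
#' @export
compute_rx_factor <- function(n_target_ip, n_spike_ip,
                              n_target_input, n_spike_input) {
  counts <- c(n_target_ip = n_target_ip, n_spike_ip = n_spike_ip,
              n_target_input = n_target_input, n_spike_input = n_spike_input)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all spike-in counts must be positive: ",
         paste(names(counts)[counts <= 0 | !is.finite(counts)], collapse = ", "))
  (n_spike_input / n_target_input) / (n_spike_ip / n_target_ip)
}

#' Read a spike-in read-count table
#'
#' TSV with header: sample, n_target_ip, n_spike_ip, n_target_input,
#' n_spike_input.
#'
#' @param path TSV path
#' @return data.frame with an added `rx_factor` column
#' @export
read_spikein_counts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample", "n_target_ip", "n_spike_ip",
            "n_target_input", "n_spike_input")
  if (!all(need %in% names(tab)))
    stop("spike-in table must have columns: ", paste(need, collapse = ", "))
  tab$rx_factor <- mapply(compute_rx_factor, tab$n_target_ip, tab$n_spike_ip,
                          tab$n_target_input, tab$n_spike_input)
  tab
}
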
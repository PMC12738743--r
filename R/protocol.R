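# Session protocol: one recording session of four phases - a baseline block
# (rest + both motor tasks), three neurofeedback training blocks (rest +
# 60 s beta downregulation), then one block per motor task combining a
# pre-neurofeedback execution, a neurofeedback phase, and a
# post-neurofeedback execution. The foot-stomping block always precedes the
# hand pronation-supination block.

#' Build a session protocol
#'
#' Returns the segment table of a full recording session. Rest and
#' neurofeedback phases default to 60 s, the inter-task rest to 35 s; task
#' windows are variable-length and default to 15 s (ten movement
#' repetitions plus margins).
#'
#' @param blocks which blocks to include, in session order. Any subset of
#'   `c("baseline", "nf1", "nf2", "nf3", "fs", "hps")`; `fs` must precede
#'   `hps` when both are present.
#' @param rest_s duration of each block-initial rest period in seconds
#' @param nf_s duration of each neurofeedback downregulation phase
#' @param task_s duration of each motor-task window
#' @param inter_rest_s rest inserted between/before repeated task phases
#' @return object of class `session_protocol`: a data.frame with columns
#'   `block`, `label`, `t_start_s`, `t_end_s` (half-open, contiguous)
#' @examples
#' proto <- session_protocol()
#' subset(proto, block == "nf3")
#' @export
session_protocol <- function(blocks = c("baseline", "nf1", "nf2", "nf3",
                                        "fs", "hps"),
                             rest_s = 60, nf_s = 60, task_s = 15,
                             inter_rest_s = 35) {
  known <- c("baseline", "nf1", "nf2", "nf3", "fs", "hps")
  if (!all(blocks %in% known)) {
    stop("unknown block(s): ", paste(setdiff(blocks, known), collapse = ", "))
  }
  if (all(c("fs", "hps") %in% blocks) &&
      which(blocks == "fs") > which(blocks == "hps")) {
    stop("the FS block must precede the HPS block")
  }
  block_segments <- function(blk) {
    switch(blk,
      baseline = data.frame(
        label = c("rest", "fs_task", "inter_rest", "hps_task"),
        dur = c(rest_s, task_s, inter_rest_s, task_s)),
      nf1 = , nf2 = , nf3 = data.frame(
        label = c("rest", "nf"),
        dur = c(rest_s, nf_s)),
      fs = , hps = data.frame(
        label = c("rest", "task_pre", "inter_rest", "nf", "task_post"),
        dur = c(rest_s, task_s, inter_rest_s, nf_s, task_s)))
  }
  t0 <- 0
  rows <- list()
  for (blk in blocks) {
    seg <- block_segments(blk)
    ends <- t0 + cumsum(seg$dur)
    rows[[blk]] <- data.frame(block = blk, label = seg$label,
                              t_start_s = c(t0, ends[-length(ends)]),
                              t_end_s = ends)
    t0 <- ends[length(ends)]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("session_protocol", "data.frame")
  validate_segments(out)
  out
}

#' Total duration of a protocol in seconds
#' @param protocol a `session_protocol` or compatible segment table
#' @return duration in seconds
#' @export
protocol_duration <- function(protocol) {
  max(protocol$t_end_s)
}

# Returns the (t_start, t_end) window of one segment; errors when absent.
protocol_window <- function(protocol, block, label) {
  s <- protocol[protocol$block == block & protocol$label == label, ]
  if (nrow(s) == 0) stop("no segment '", label, "' in block '", block, "'")
  c(s$t_start_s[1], s$t_end_s[1])
}
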
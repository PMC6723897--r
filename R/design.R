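# Experimental design of the tablet study: a 3^3 full factorial block plus
# ten axial-style additional settings, and the 53-point dissolution sampling
# schedule.

#' Tablet experimental design
#'
#' Reconstructs the 37-setting compression study: settings 1-27 enumerate a
#' 3^3 full factorial in drug content (DR, 6/8/10 % w/w), matrix polymer
#' content (HPMC, 10/20/30 % w/w) and compression pressure
#' (63.8/95.7/127.6 MPa); settings 28-37 hold two factors at the centre
#' point while the third takes additional levels inside and outside the
#' factorial range (DR 7-9 %, HPMC 5-35 %, pressure 31.9-159.5 MPa).
#' Settings 1, 4, 14, 17, 27, 29 and 34 are held out as the external test
#' set; the remaining 30 settings are used for calibration/training.
#'
#' @return A data frame with one row per setting and columns `setting_id`,
#'   `dr_nominal`, `hpmc_nominal` (% w/w), `force` (MPa), `role`
#'   (`"train"`/`"test"`) and `origin` (`"factorial"`/`"additional"`).
#' @examples
#' d <- build_design()
#' table(d$role)
#' @export
build_design <- function() {
  fact <- expand.grid(
    dr    = c(6, 8, 10),
    hpmc  = c(10, 20, 30),
    force = c(63.8, 95.7, 127.6),
    KEEP.OUT.ATTRS = FALSE
  )
  add <- data.frame(
    dr    = c(7, 7.5, 8.5, 9, 8, 8, 8, 8, 8, 8),
    hpmc  = c(20, 20, 20, 20, 5, 15, 25, 35, 20, 20),
    force = c(rep(63.8, 8), 31.9, 159.5)
  )
  d <- rbind(fact, add)
  test_ids <- c(1L, 4L, 14L, 17L, 27L, 29L, 34L)
  data.frame(
    setting_id   = seq_len(37L),
    dr_nominal   = d$dr,
    hpmc_nominal = d$hpmc,
    force        = d$force,
    role         = ifelse(seq_len(37L) %in% test_ids, "test", "train"),
    origin       = rep(c("factorial", "additional"), c(27L, 10L)),
    stringsAsFactors = FALSE
  )
}

#' Dissolution sampling time grid
#'
#' The 53-point sampling schedule of the 24 h USP II dissolution run:
#' 2, 5, 10, 15, 30, 45 and 60 min, then every 30 min up to 1440 min.
#'
#' @return Strictly increasing numeric vector of 53 times in minutes.
#' @examples
#' length(dissolution_time_grid())
#' @export
dissolution_time_grid <- function() {
  c(2, 5, 10, 15, 30, 45, 60, seq(90, 1440, by = 30))
}
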
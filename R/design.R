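#' Button/flash layout of the display
#'
#' The five horizontal flash locations (and their response buttons), in
#' degrees visual angle relative to fixation; negative is left. Position
#' indices 1..5 run left to right, position 3 is central.
#'
#' @return Numeric vector of 5 strictly increasing azimuths (deg), symmetric
#'   about 0.
#' @export
button_layout <- function() {
  c(-5.68, -2.84, 0, 2.84, 5.68)
}

#' Map a position index to its azimuth
#'
#' @param position Integer position index in 1..5.
#' @param layout Button layout, see [button_layout()].
#' @return Azimuth in degrees visual angle.
#' @export
position_to_azimuth <- function(position, layout = button_layout()) {
  if (any(!position %in% seq_along(layout))) {
    stop("position must be in 1..", length(layout))
  }
  layout[position]
}

#' Map an azimuth back to its position index
#'
#' @param azimuth Azimuth in degrees; must be one of the layout values.
#' @param layout Button layout.
#' @return Integer position index in 1..5.
#' @export
azimuth_to_position <- function(azimuth, layout = button_layout()) {
  idx <- match(azimuth, layout)
  if (any(is.na(idx))) stop("azimuth not in layout")
  idx
}

# nominal within-modality event onsets (ms); 58 ms spacing so that the fixed
# temporal prior means are centred on the synchronous stimuli
.onsets_base <- c(47, 105, 163)
.asynchrony_lag_ms <- 225
.physical_soa_ms <- 75  # physical flash/beep onset spacing; metadata only

#' Build the canonical 28-condition audiovisual rabbit design
#'
#' Reconstructs the full stimulus design of the illusory / invisible
#' audiovisual rabbit experiment: three-event flash-beep sequences over five
#' horizontal positions, with synchronous, auditory-lead and visual-lead
#' timing, left/right mirror directions, direction-changing bias-control
#' sequences, and unisensory (0-beep) plus multisensory controls.
#'
#' Composition (28 conditions):
#' \itemize{
#'   \item illusory rabbit (2 flashes + 3 beeps): sync/A-lead/V-lead x L/R (6)
#'   \item invisible rabbit (3 flashes + 2 beeps): sync/A-lead/V-lead x L/R (6)
#'   \item unisensory controls (0 beeps): 2-flash L/R, 3-flash L/R,
#'     3-flash direction-changing type 1/2 (6)
#'   \item multisensory controls: 2F2B L/R sync, 3F3B L/R sync, 3F3B
#'     direction-changing type 1/2 x sync/A-lead/V-lead (10)
#' }
#' Twelve conditions are asynchronous; 8 of the 18 conditions with a flash at
#' the second event change direction. Every first flash is central
#' (position 3). In asynchronous conditions the leading modality keeps onsets
#' \{47, 105, 163\} ms and the lagging modality is shifted by +225 ms.
#'
#' Absent stimuli are carried as intensity-0 events on the design's latent
#' position/time grid, which is what the generative observer model consumes.
#'
#' @param trials_per_condition Trials per condition (default 28).
#' @param catch_rate Proportion of catch trials in a session (default 0.0666).
#' @return An object of class `rabbit_design`: list with `conditions`
#'   (condition-level data.frame), `events` (one row per condition x event),
#'   `layout`, `trials_per_condition`, `catch_rate`.
#' @export
build_design <- function(trials_per_condition = 28, catch_rate = 0.0666) {
  layout <- button_layout()

  # position sequences on the latent 3-event grid
  seq_pos <- list(
    right        = c(3, 4, 5),
    left         = c(3, 2, 1),
    change_type1 = c(3, 4, 1),
    change_type2 = c(3, 2, 5)
  )
  # illusion-analog response pattern: for 2-flash conditions the extra middle
  # flash ("3-4-5"/"3-2-1"); for 3-flash conditions the suppressed middle
  # flash ("3-5"/"3-1"). Veridical match pattern is the presented sequence.
  patt <- function(pos, v_present) {
    paste(pos[v_present], collapse = "-")
  }
  illusion_patt <- function(pos, n_flash) {
    if (n_flash == 2) patt(pos, c(TRUE, TRUE, TRUE)) else patt(pos, c(TRUE, FALSE, TRUE))
  }
  match_patt <- function(pos, n_flash) {
    if (n_flash == 2) patt(pos, c(TRUE, FALSE, TRUE)) else patt(pos, c(TRUE, TRUE, TRUE))
  }

  onsets <- function(asynchrony) {
    base <- .onsets_base
    lag <- base + .asynchrony_lag_ms
    switch(asynchrony,
      sync   = list(A = base, V = base),
      a_lead = list(A = base, V = lag),
      v_lead = list(A = lag,  V = base)
    )
  }

  rows <- list()
  add <- function(id, direction, asynchrony, category, v_present, a_present) {
    pos <- seq_pos[[direction]]
    n_flash <- sum(v_present)
    rows[[length(rows) + 1L]] <<- list(
      condition_id = id, direction = direction, asynchrony = asynchrony,
      category = category, positions = pos, v_present = v_present,
      a_present = a_present, n_flashes = n_flash, n_beeps = sum(a_present),
      illusion_patterns = illusion_patt(pos, n_flash),
      match_pattern = match_patt(pos, n_flash)
    )
  }

  two_fl <- c(TRUE, FALSE, TRUE)   # flashes at events 1 and 3
  three  <- rep(TRUE, 3)
  none   <- rep(FALSE, 3)

  for (dir in c("right", "left")) {
    d <- toupper(substr(dir, 1, 1))
    for (asy in c("sync", "a_lead", "v_lead")) {
      a <- c(sync = "SYNC", a_lead = "ALEAD", v_lead = "VLEAD")[[asy]]
      # illusory rabbit: 2 flashes + 3 beeps
      add(paste0("ILL-", d, "-", a), dir, asy, "illusory", two_fl, three)
      # invisible rabbit: 3 flashes + 2 beeps (no middle beep)
      add(paste0("INV-", d, "-", a), dir, asy, "invisible", three, two_fl)
    }
    # unisensory controls (0 beeps)
    add(paste0("U2F-", d), dir, "sync", "uni_ctrl", two_fl, none)
    add(paste0("U3F-", d), dir, "sync", "uni_ctrl", three, none)
    # multisensory controls
    add(paste0("M2F2B-", d), dir, "sync", "multi_ctrl", two_fl, two_fl)
    add(paste0("M3F3B-", d), dir, "sync", "multi_ctrl", three, three)
  }
  # direction-changing bias controls (all 3-flash)
  for (ty in c("change_type1", "change_type2")) {
    t <- ifelse(ty == "change_type1", "T1", "T2")
    add(paste0("U3F-", t), ty, "sync", "uni_ctrl", three, none)
    for (asy in c("sync", "a_lead", "v_lead")) {
      a <- c(sync = "SYNC", a_lead = "ALEAD", v_lead = "VLEAD")[[asy]]
      add(paste0("M3F3B-", t, "-", a), ty, asy, "multi_ctrl", three, three)
    }
  }

  conditions <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      condition_id = r$condition_id, direction = r$direction,
      asynchrony = r$asynchrony, category = r$category,
      n_flashes = r$n_flashes, n_beeps = r$n_beeps,
      illusion_patterns = r$illusion_patterns, match_pattern = r$match_pattern,
      stringsAsFactors = FALSE
    )
  }))

  events <- do.call(rbind, lapply(rows, function(r) {
    on <- onsets(r$asynchrony)
    data.frame(
      condition_id = r$condition_id, event = 1:3,
      A_present = r$a_present, V_present = r$v_present,
      V_position = r$positions,
      A_onset_ms = on$A, V_onset_ms = on$V,
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(conditions = conditions, events = events, layout = layout,
         trials_per_condition = trials_per_condition, catch_rate = catch_rate,
         physical_soa_ms = .physical_soa_ms),
    class = "rabbit_design"
  )
}

#' @export
print.rabbit_design <- function(x, ...) {
  cat("Audiovisual rabbit design:", nrow(x$conditions), "conditions,",
      sum(x$conditions$asynchrony != "sync"), "asynchronous;",
      x$trials_per_condition, "trials/condition, catch rate",
      x$catch_rate, "\n")
  invisible(x)
}

#' Extract one condition from a design
#'
#' @param design A `rabbit_design`.
#' @param condition_id Condition identifier.
#' @return List with the condition's metadata, its 3 event rows, parsed
#'   illusion/match patterns and the layout.
#' @export
get_condition <- function(design, condition_id) {
  meta <- design$conditions[design$conditions$condition_id == condition_id, ]
  if (nrow(meta) != 1L) stop("unknown condition_id: ", condition_id)
  ev <- design$events[design$events$condition_id == condition_id, ]
  ev <- ev[order(ev$event), ]
  list(
    condition_id = condition_id,
    direction = meta$direction, asynchrony = meta$asynchrony,
    category = meta$category, n_flashes = meta$n_flashes,
    n_beeps = meta$n_beeps,
    illusion_patterns = parse_patterns(meta$illusion_patterns),
    match_pattern = parse_patterns(meta$match_pattern)[[1]],
    events = ev, layout = design$layout
  )
}

#' @export
condition_ids <- function(design) design$conditions$condition_id

# "3-4-5;3-2-1" -> list(c(3,4,5), c(3,2,1))
parse_patterns <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE)[[1]], function(p) {
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  })
}

#' Event onset table for one condition
#'
#' The 3 x 2 onset table (auditory, visual; ms) used as the distal temporal
#' stimulus values of the generative model.
#'
#' @param condition A condition from [get_condition()].
#' @return data.frame with columns `event`, `auditory_onset_ms`,
#'   `visual_onset_ms`.
#' @export
event_times <- function(condition) {
  data.frame(
    event = condition$events$event,
    auditory_onset_ms = condition$events$A_onset_ms,
    visual_onset_ms = condition$events$V_onset_ms
  )
}

#' Distal stimulus matrix for one condition
#'
#' One row per event; columns `S_A`, `T_A`, `I_A`, `S_V`, `T_V`, `I_V`.
#' Auditory azimuth is 0 (central loudspeaker); absent stimuli have
#' intensity 0 but keep their latent grid location and time.
#'
#' @param condition A condition from [get_condition()].
#' @return 3 x 6 numeric matrix.
#' @export
distal_stimulus <- function(condition) {
  ev <- condition$events
  m <- cbind(
    S_A = rep(0, 3),
    T_A = ev$A_onset_ms,
    I_A = as.numeric(ev$A_present),
    S_V = position_to_azimuth(ev$V_position, condition$layout),
    T_V = ev$V_onset_ms,
    I_V = as.numeric(ev$V_present)
  )
  rownames(m) <- paste0("event", 1:3)
  m
}

#' Is a condition modelled visual-only?
#'
#' Zero-beep (unisensory) conditions are processed through the visual
#' segregation path for every model variant: no auditory input is received,
#' so there is no causal inference to perform.
#'
#' @param condition A condition from [get_condition()].
#' @export
is_visual_only <- function(condition) condition$n_beeps == 0L

#' Analysis-condition label used for direction pooling
#'
#' Maps each of the 28 conditions to one of the ten analysis conditions
#' (two illusions x \{uni ctrl, multi ctrl, sync, A-lead, V-lead\});
#' direction-changing bias-control conditions map to `NA` and are excluded
#' from the pooled analysis set.
#'
#' @param design A `rabbit_design`.
#' @return Named character vector (by condition_id).
#' @export
analysis_condition <- function(design) {
  cond <- design$conditions
  side <- ifelse(cond$n_flashes == 2, "illusory", "invisible")
  lab <- ifelse(
    cond$direction %in% c("change_type1", "change_type2"), NA_character_,
    ifelse(cond$category == "uni_ctrl", paste0(side, "_uni_ctrl"),
    ifelse(cond$category == "multi_ctrl", paste0(side, "_multi_ctrl"),
           paste0(cond$category, "_", cond$asynchrony))))
  stats::setNames(lab, cond$condition_id)
}

#' Write / read a design as a tab-separated condition table
#'
#' One row per condition x event with the condition-level metadata repeated,
#' so the reconstruction of the stimulus table is auditable and overridable.
#'
#' @param design A `rabbit_design`.
#' @param path Output file path.
#' @export
write_design <- function(design, path) {
  tab <- merge(design$events, design$conditions, by = "condition_id",
               sort = FALSE)
  tab <- tab[order(match(tab$condition_id, design$conditions$condition_id),
                   tab$event), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# audiovisual rabbit condition table; trials_per_condition=",
           design$trials_per_condition, " catch_rate=", design$catch_rate),
    paste0("# layout_deg=", paste(design$layout, collapse = ","))
  ), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  layout <- button_layout()
  tpc <- 28; cr <- 0.0666
  for (h in lines[hdr]) {
    if (grepl("layout_deg=", h)) {
      layout <- as.numeric(strsplit(sub(".*layout_deg=", "", h), ",")[[1]])
    }
    if (grepl("trials_per_condition=", h)) {
      tpc <- as.integer(sub(".*trials_per_condition=(\\d+).*", "\\1", h))
      cr <- as.numeric(sub(".*catch_rate=([0-9.]+).*", "\\1", h))
    }
  }
  tab <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  cond_cols <- c("condition_id", "direction", "asynchrony", "category",
                 "n_flashes", "n_beeps", "illusion_patterns", "match_pattern")
  conditions <- unique(tab[, cond_cols])
  rownames(conditions) <- NULL
  events <- tab[, c("condition_id", "event", "A_present", "V_present",
                    "V_position", "A_onset_ms", "V_onset_ms")]
  structure(
    list(conditions = conditions, events = events, layout = layout,
         trials_per_condition = tpc, catch_rate = cr,
         physical_soa_ms = .physical_soa_ms),
    class = "rabbit_design"
  )
}
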
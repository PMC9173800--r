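#' Stimulus specification
#'
#' Describes one full-field stimulus: a flash (or 30-Hz flicker train) of a
#' given photopic strength delivered either in the dark, on a dim blue
#' rod-saturating background, or on the standard white photopic background.
#'
#' @param label Protocol label, e.g. `"DA 3"` or `"X67-blue"`.
#' @param flash_strength Flash strength in photopic cd m^-2 s (> 0).
#' @param background_kind One of `"dark"`, `"blue_rod_saturating"`,
#'   `"white_photopic"`.
#' @param background_scotopic_luminance Scotopic background luminance in
#'   scotopic cd m^-2.  Defaults: 0 in the dark, 30 on the blue background.
#' @param background_photopic_luminance Photopic background luminance in
#'   photopic cd m^-2.  Defaults: 0 in the dark, 1 on the blue background,
#'   30 on the white background.
#' @param mode `"single_flash"` or `"flicker_30hz"`.
#'
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec("DA 3", 3)
#' stimulus_spec("LA 30Hz", 3, "white_photopic", mode = "flicker_30hz")
stimulus_spec <- function(label, flash_strength,
                          background_kind = c("dark", "blue_rod_saturating",
                                              "white_photopic"),
                          background_scotopic_luminance = NULL,
                          background_photopic_luminance = NULL,
                          mode = c("single_flash", "flicker_30hz")) {
  background_kind <- match.arg(background_kind)
  mode <- match.arg(mode)
  if (!is.numeric(flash_strength) || length(flash_strength) != 1L ||
      !is.finite(flash_strength) || flash_strength <= 0) {
    stop("`flash_strength` must be a single positive number (photopic cd m^-2 s)")
  }
  defaults <- switch(background_kind,
    dark = c(scot = 0, phot = 0),
    blue_rod_saturating = c(scot = 30, phot = 1),
    white_photopic = c(scot = 0, phot = 30))
  scot <- if (is.null(background_scotopic_luminance)) defaults[["scot"]] else
    background_scotopic_luminance
  phot <- if (is.null(background_photopic_luminance)) defaults[["phot"]] else
    background_photopic_luminance
  if (background_kind == "dark" && (scot != 0 || phot != 0)) {
    stop("a dark-condition stimulus must have zero background luminance")
  }
  structure(list(label = label,
                 flash_strength = flash_strength,
                 background_kind = background_kind,
                 background_scotopic_luminance = scot,
                 background_photopic_luminance = phot,
                 mode = mode),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus '%s'> %.3g cd.m-2.s, background = %s, mode = %s\n",
              x$label, x$flash_strength, x$background_kind, x$mode))
  invisible(x)
}

#' The full recording protocol
#'
#' The stimulus set used throughout: the ISCEV dark-adapted flashes
#' (DA 0.01 / DA 3 / DA 10), four xenon flash strengths (0.67, 4.0, 13 and
#' 67 photopic cd m^-2 s) each delivered in the dark and on the blue
#' rod-saturating background, and the light-adapted 30-Hz flicker and LA 3
#' flash on the standard white photopic background.
#'
#' @param which `"all"`, `"iscev"` (DA/LA standards only) or `"xenon"`
#'   (the dark/blue flash pairs only).
#' @return A named list of [stimulus_spec()] objects.
#' @export
standard_protocol <- function(which = c("all", "iscev", "xenon")) {
  which <- match.arg(which)
  xs <- c(0.67, 4.0, 13, 67)
  iscev <- list(
    stimulus_spec("DA 0.01", 0.01, "dark"),
    stimulus_spec("DA 3", 3, "dark"),
    stimulus_spec("DA 10", 10, "dark"),
    stimulus_spec("LA 30Hz", 3, "white_photopic", mode = "flicker_30hz"),
    stimulus_spec("LA 3", 3, "white_photopic"))
  xenon <- c(
    lapply(xs, function(s) stimulus_spec(sprintf("X%g-dark", s), s, "dark")),
    lapply(xs, function(s) stimulus_spec(sprintf("X%g-blue", s), s,
                                         "blue_rod_saturating")))
  out <- switch(which, all = c(iscev, xenon), iscev = iscev, xenon = xenon)
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Xenon flash strengths used for rod/cone separation
#' @return Numeric vector of photopic cd m^-2 s values.
#' @export
xenon_strengths <- function() c(0.67, 4.0, 13, 67)

#' Read a protocol definition file
#'
#' Loads a JSON protocol config (a list of [stimulus_spec()] field sets).
#' The standard set ships with the package at
#' `system.file("extdata", "standard_protocol.json", package = "ergdose")`.
#'
#' @param path Path to a protocol JSON file.
#' @return A named list of [stimulus_spec()] objects.
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(s) do.call(stimulus_spec, s))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
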
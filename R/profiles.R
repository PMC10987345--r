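#' Define a stain-class HSV window profile
#'
#' A profile is the set of closed HSV intervals that defines one stain
#' class: a pixel belongs to the class when its hue falls in *any* hue
#' window and its saturation and value fall in the respective windows. All
#' bounds are inclusive. A wrap-around hue range (e.g. the DAB browns that
#' straddle 0 degrees) is expressed as two windows.
#'
#' @param name stain-class label, e.g. `"ihc"` or `"nucleus"`.
#' @param hue_windows list of length-2 numeric vectors `c(low, high)` in
#'   degrees, each with `low <= high`, within `[0, 360]`.
#' @param sat_window,val_window length-2 numeric vectors on `[0, 255]`.
#' @return An object of class `channel_profile`.
#' @export
channel_profile <- function(name, hue_windows, sat_window = c(0, 255),
                            val_window = c(0, 255)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("profile 'name' must be a non-empty string")
  if (is.numeric(hue_windows)) hue_windows <- list(hue_windows)
  ok_win <- function(w, lo, hi) is.numeric(w) && length(w) == 2L &&
    !anyNA(w) && w[1] <= w[2] && w[1] >= lo && w[2] <= hi
  if (!length(hue_windows) || !all(vapply(hue_windows, ok_win, logical(1), 0, 360)))
    stop_validation("each hue window must be c(low, high) with 0 <= low <= high <= 360")
  if (!ok_win(sat_window, 0, 255)) stop_validation("sat_window must be c(low, high) in [0, 255]")
  if (!ok_win(val_window, 0, 255)) stop_validation("val_window must be c(low, high) in [0, 255]")
  structure(list(name = name,
                 hue_windows = lapply(hue_windows, as.numeric),
                 sat_window = as.numeric(sat_window),
                 val_window = as.numeric(val_window)),
            class = "channel_profile")
}

#' @export
print.channel_profile <- function(x, ...) {
  hw <- paste(vapply(x$hue_windows, function(w) sprintf("[%g,%g]", w[1], w[2]),
                     character(1)), collapse = " U ")
  cat(sprintf("<channel_profile '%s'> hue %s deg, S [%g,%g], V [%g,%g]\n",
              x$name, hw, x$sat_window[1], x$sat_window[2],
              x$val_window[1], x$val_window[2]))
  invisible(x)
}

#' Default DAB and hematoxylin profiles
#'
#' The windows separating the brown DAB chromogen (IHC signal) from the
#' blue hematoxylin counterstain on 8-bit brightfield scans: IHC hue
#' 0-60 and 320-360 degrees, saturation 60-255, value 0-160; nucleus hue
#' 200-320 degrees, saturation 20-255, value 10-220. The two hue ranges
#' are disjoint, so the two masks can never share a pixel.
#'
#' @return A named list with `channel_profile` elements `ihc` and `nucleus`.
#' @examples
#' default_profiles()$ihc
#' @export
default_profiles <- function() {
  list(
    ihc = channel_profile("ihc",
                          hue_windows = list(c(0, 60), c(320, 360)),
                          sat_window = c(60, 255),
                          val_window = c(0, 160)),
    nucleus = channel_profile("nucleus",
                              hue_windows = list(c(200, 320)),
                              sat_window = c(20, 255),
                              val_window = c(10, 220))
  )
}

#' Read or write stain profiles as a YAML config file
#'
#' The file maps profile names to `hue_windows` (list of `[low, high]`
#' pairs in degrees), `sat_window` and `val_window`.
#'
#' @param profiles named list of [channel_profile] objects.
#' @param path config file path.
#' @return `read_profiles()` returns a named list of profiles;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  ser <- lapply(profiles, function(p)
    list(hue_windows = p$hue_windows, sat_window = p$sat_window,
         val_window = p$val_window))
  atomic_write(path, function(pth) yaml::write_yaml(ser, pth))
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("profile config not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    channel_profile(nm, hue_windows = lapply(p$hue_windows, unlist),
                    sat_window = unlist(p$sat_window),
                    val_window = unlist(p$val_window))
  })
  names(out) <- names(raw)
  out
}
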
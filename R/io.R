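# Readers/writers: multi-page 8-bit TIFF stacks with JSON sidecars, tidy CSV
# for agent tables, ring traces and profile series.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write / read an image stack
#'
#' Stacks are stored as multi-page 8-bit grayscale TIFF plus a JSON sidecar
#' (`pixel_size_um`, `frame_times_min`) next to the TIFF. The round trip is
#' lossless for 8-bit integer frames.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path (sidecar written beside it).
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 255),
                  path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size,
         frame_times_min = stack$frame_times),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param default_pixel_size fallback (um/px) when the sidecar is missing.
#' @rdname write_stack
#' @export
read_stack <- function(path, default_pixel_size = 2.0) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    round(f * 255)
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("read_stack: pages differ in shape", call. = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    ps <- meta$pixel_size_um
    ft <- as.numeric(meta$frame_times_min)
    if (length(ft) != length(frames))
      stop("read_stack: sidecar frame_times length mismatch", call. = FALSE)
    if (any(diff(ft) <= 0))
      stop("read_stack: frame_times must be strictly increasing", call. = FALSE)
  } else {
    warning("read_stack: sidecar missing; assuming pixel_size = ",
            default_pixel_size, " um/px and unit frame interval")
    ps <- default_pixel_size
    ft <- seq_along(frames) - 1
  }
  image_stack(frames, ps, ft)
}

#' Write tidy CSV outputs
#'
#' `write_agents_csv` stores an agent table (`id`, `t_min`, `x_um`, `y_um`,
#' `state`); `write_profiles_csv` stores a radial-profile series as one
#' observation per row (`time_min`, `bin_center_um`, `value`, `n_px`) with a
#' JSON sidecar holding the centre and bin width; `read_profiles_csv`
#' rebuilds the list of [radial_profile()] objects.
#'
#' @param agents agent table.
#' @param profiles list of [radial_profile()]s.
#' @param path file path.
#' @return the path, invisibly (readers return the parsed object).
#' @export
write_agents_csv <- function(agents, path) {
  utils::write.csv(agents[, c("id", "t_min", "x_um", "y_um", "state")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agents_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  tall <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(time_min = attr(p, "t_min"), bin_center_um = p$bin_center_um,
               value = p$relative_density, n_px = p$n_px)
  }))
  utils::write.csv(tall, path, row.names = FALSE)
  p1 <- profiles[[1]]
  jsonlite::write_json(list(center_um = attr(p1, "center"),
                            bin_width_um = attr(p1, "bin_width")),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_agents_csv
#' @export
read_profiles_csv <- function(path) {
  tall <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  lapply(split(tall, tall$time_min), function(d) {
    structure(
      data.frame(bin_center_um = d$bin_center_um,
                 relative_density = d$value, n_px = d$n_px),
      center = as.numeric(meta$center_um), t_min = d$time_min[1],
      bin_width = meta$bin_width_um,
      class = c("radial_profile", "data.frame"))
  })
}
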
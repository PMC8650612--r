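# Bright-field-like rasterisation of agent snapshots.

#' Render one frame from an agent snapshot
#'
#' Each in-view agent is drawn as a radially symmetric Gaussian intensity
#' bump (sd = `cell_render_radius / 2`, support truncated at
#' `cell_render_radius`) added to a dark background; Gaussian noise of sd
#' `noise_sd` is added and the result rounded and clipped to 8 bits. Agents
#' outside the frame simply contribute nothing.
#'
#' Rendering consumes the R RNG (for the noise), so wrap calls in
#' `set.seed()` when bit-identical stacks are required; [render_frames()]
#' does this from `params$seed`.
#'
#' @param agents agent snapshot (data.frame with `x_um`, `y_um`).
#' @param params a [colony_params()] object (geometry and render settings).
#' @return numeric matrix `image_size` x `image_size` with values in 0..255.
#' @export
render_frame <- function(agents, params) {
  render_frame_cpp(agents$x_um, agents$y_um,
                   params$image_size, params$pixel_size,
                   params$cell_render_radius, params$cell_intensity,
                   params$background, params$noise_sd)
}

#' Image stack container
#'
#' @param frames list of equally shaped numeric matrices.
#' @param pixel_size um/px.
#' @param frame_times strictly increasing times (min), one per frame.
#' @return an `image_stack` list.
#' @export
image_stack <- function(frames, pixel_size, frame_times) {
  if (length(frames) != length(frame_times))
    stop("image_stack: one frame time per frame required", call. = FALSE)
  if (length(frames) > 1) {
    d <- dim(frames[[1]])
    same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(same)) stop("image_stack: frames differ in shape", call. = FALSE)
    if (any(diff(frame_times) <= 0))
      stop("image_stack: frame_times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_times = frame_times), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat("<image_stack>", length(x$frames), "frames", d[1], "x", d[2],
      "px @", x$pixel_size, "um/px\n")
  invisible(x)
}

#' Render an image stack from a simulation
#'
#' @param sim a `colony_sim` from [simulate_colony()].
#' @param times frame times to render (default: all recorded snapshots).
#' @return an [image_stack()].
#' @export
render_frames <- function(sim, times = sim$frame_times) {
  set.seed(sim$params$seed + 1000003L)   # independent noise stream, reproducible
  frames <- lapply(times, function(tt) render_frame(agents_at(sim, tt), sim$params))
  image_stack(frames, sim$params$pixel_size, times)
}
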
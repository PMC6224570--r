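# Unit conventions: hartree / radians / atomic time units internally,
# eV / degrees / femtoseconds at user interfaces; g and dipoles in au
# everywhere.

HARTREE_EV <- 27.211386245988
FS_AU <- 41.34137333656137   # 1 fs in atomic time units
KB_HA <- 3.166811563e-6      # Boltzmann constant, hartree / K

#' Unit conversion helpers
#'
#' The package works in atomic units internally (hartree, radians, atomic
#' time) and exposes eV, degrees and femtoseconds at its interfaces.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
ev_to_hartree <- function(x) x / HARTREE_EV

#' @rdname units
#' @export
hartree_to_ev <- function(x) x * HARTREE_EV

#' @rdname units
#' @export
fs_to_au <- function(x) x * FS_AU

#' @rdname units
#' @export
au_to_fs <- function(x) x / FS_AU

#' @rdname units
#' @export
deg_to_rad <- function(x) x * pi / 180

#' @rdname units
#' @export
rad_to_deg <- function(x) x * 180 / pi

#' Boltzmann constant in hartree per kelvin
#' @export
kB_hartree <- function() KB_HA
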
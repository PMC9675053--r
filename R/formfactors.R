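# Atomic scattering factors: 4-Gaussian Cromer-Mann parameterization
# f(s) = sum_j a_j exp(-b_j s^2) + c with s = |q| / (4 pi) = sin(theta)/lambda.
# Coefficients are the International Tables vol. C values for neutral atoms
# (elements that occur in biomolecules plus common counter-ions). Anomalous
# dispersion is neglected: light elements dominate at 6 keV.

.cromer_mann <- local({
  tab <- list(
    #        Z    a1        a2        a3        a4        b1        b2        b3        b4        c
    H  = c( 1, 0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257,  3.14236, 57.7997,  0.003038),
    C  = c( 6, 2.310000, 1.020000, 1.588600, 0.865000, 20.8439, 10.2075,  0.56870, 51.6512,  0.215600),
    N  = c( 7, 12.21260, 3.132200, 2.012500, 1.166300,  0.0057,  9.8933, 28.99750,  0.5826, -11.52900),
    O  = c( 8, 3.048500, 2.286800, 1.546300, 0.867000, 13.2771,  5.7011,  0.32390, 32.9089,  0.250800),
    "NA" = c(11, 4.762600, 3.173600, 1.267400, 1.112800,  3.2850,  8.8422,  0.31360, 129.424,  0.676000),
    "MG" = c(12, 5.420400, 2.173500, 1.226900, 2.307300,  2.8275, 79.2611,  0.38080,  7.1937,  0.858400),
    P  = c(15, 6.434500, 4.179100, 1.780000, 1.490800,  1.9067, 27.1570,  0.52600, 68.1645,  1.114900),
    S  = c(16, 6.905300, 5.203400, 1.437900, 1.586300,  1.4679, 22.2151,  0.25360, 56.1720,  0.866900),
    "CL" = c(17, 11.46040, 7.196400, 6.255600, 1.645500,  0.0104,  1.1662, 18.51940, 47.7784, -9.557400),
    K  = c(19, 8.218600, 7.439800, 1.051900, 0.865900, 12.7949,  0.7748, 213.1870, 41.6841,  1.422800),
    "CA" = c(20, 8.626600, 7.387300, 1.589900, 1.021100, 10.4421,  0.6599, 85.74840, 178.437,  1.375100),
    "MN" = c(25, 11.28190, 7.357300, 3.019300, 2.244100,  5.3409,  0.3432, 17.86740, 83.7543,  1.089600),
    "FE" = c(26, 11.76950, 7.357300, 3.522200, 2.304500,  4.7611,  0.3072, 15.35350, 76.8805,  1.036900),
    "ZN" = c(30, 14.07430, 7.031800, 5.165200, 2.410000,  3.2655,  0.2333, 10.31630, 58.7097,  1.304100),
    "SE" = c(34, 17.00060, 5.819600, 3.973100, 4.354300,  2.4098,  0.2726, 15.23720, 43.8163,  2.840900))
  m <- do.call(rbind, tab)
  colnames(m) <- c("Z", paste0("a", 1:4), paste0("b", 1:4), "c")
  m
})

#' Elements with tabulated scattering factors
#' @return Character vector of element symbols.
#' @export
known_elements <- function() rownames(.cromer_mann)

.norm_element <- function(elements) toupper(trimws(elements))

#' Atomic number lookup
#' @param elements Character vector of element symbols.
#' @return Integer atomic numbers.
#' @export
atomic_number <- function(elements) {
  e <- .norm_element(elements)
  bad <- !(e %in% rownames(.cromer_mann))
  if (any(bad))
    stop("unknown element symbol(s): ", paste(unique(elements[bad]), collapse = ", "))
  as.integer(.cromer_mann[e, "Z"])
}

#' Atomic scattering factor f(q)
#'
#' @param elements Character vector of element symbols (recycled against `q`
#'   if of length one, otherwise an outer table is returned).
#' @param q Scattering-vector magnitudes in Angstrom^-1.
#' @return If `elements` has length one, a numeric vector `f(q)`; otherwise a
#'   `length(q) x length(elements)` matrix. `f(0)` equals the atomic number.
#' @export
form_factor <- function(elements, q) {
  e <- .norm_element(elements)
  atomic_number(e)  # validates
  s2 <- (q / (4 * pi))^2
  out <- vapply(e, function(el) {
    p <- .cromer_mann[el, ]
    p[["c"]] + p[["a1"]] * exp(-p[["b1"]] * s2) + p[["a2"]] * exp(-p[["b2"]] * s2) +
      p[["a3"]] * exp(-p[["b3"]] * s2) + p[["a4"]] * exp(-p[["b4"]] * s2)
  }, numeric(length(q)))
  out <- matrix(out, nrow = length(q), ncol = length(e),
                dimnames = list(NULL, e))
  if (length(e) == 1L) as.numeric(out) else out
}
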
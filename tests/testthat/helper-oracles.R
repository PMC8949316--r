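## Independent backbone-enumeration oracle for lipid formulas: assembles the
## molecule from explicit building blocks (glycerol, fatty acids/enol ethers,
## sphingoid bases, headgroups) with one water lost per condensation. This is
## a different construction from the package's closed-form per-class rules.

oracleAtoms <- function(...) {
  v <- c(C = 0, H = 0, O = 0, N = 0, P = 0, S = 0)
  args <- list(...)
  for (a in args) v[names(a)] <- v[names(a)] + a
  v
}
.water <- c(H = 2, O = 1)
.glycerol <- c(C = 3, H = 8, O = 3)
.phosphoric <- c(H = 3, O = 4, P = 1)
.ethanolamine <- c(C = 2, H = 7, N = 1, O = 1)
.choline <- c(C = 5, H = 13, N = 1, O = 1)
.serine <- c(C = 3, H = 7, N = 1, O = 3)
.inositol <- c(C = 6, H = 12, O = 6)
.hexose <- c(C = 6, H = 12, O = 6)

## fatty acid with n carbons / d double bonds, e.g. 16:0 = C16H32O2
.fattyAcid <- function(n, d) c(C = n, H = 2 * n - 2 * d, O = 2)
## 1-alkenyl enol (vinyl-ether precursor), e.g. C16 enol = C16H32O
.enolEther <- function(n, d) c(C = n, H = 2 * n - 2 * d, O = 1)
## sphingoid bases: dihydroxy C_s H_{2s+3-2b} N O2 (e.g. sphinganine
## C18H39NO2, sphingosine C18H37NO2), trihydroxy adds one O
.sphingoid <- function(s, b, hyd) {
  c(C = s, H = 2 * s + 3 - 2 * b, N = 1, O = if (hyd == "d") 2 else 3)
}

minusWater <- function(v, n = 1) {
  v["H"] <- v["H"] - 2 * n
  v["O"] <- v["O"] - n
  v
}

## Assemble a sum-composition species by splitting the chain totals into two
## plausible chains (the formula depends only on totals, so any split works;
## 18:0/20:4 is used for 38:4-style species).
formulaOracle <- function(class, carbons, doubleBonds, hydroxylation = "none") {
  n1 <- if (carbons >= 36) 18 else 16
  d1 <- 0
  n2 <- carbons - n1
  d2 <- doubleBonds
  glycero2 <- function(head) {
    ## glycerol + 2 FA esters + phosphodiester to headgroup: 4 condensations
    minusWater(oracleAtoms(.glycerol, .fattyAcid(n1, d1), .fattyAcid(n2, d2),
                           .phosphoric, head), 4)
  }
  cer <- function() {
    ## amide condensation of base (18 C) and fatty acid
    minusWater(oracleAtoms(.sphingoid(18, if (hydroxylation == "d") 1 else 0,
                                      hydroxylation),
                           .fattyAcid(carbons - 18,
                                      doubleBonds -
                                        (if (hydroxylation == "d") 1 else 0))),
               1)
  }
  switch(class,
    PE = glycero2(.ethanolamine),
    PC = glycero2(.choline),
    PS = glycero2(.serine),
    PI = glycero2(.inositol),
    PG = glycero2(.glycerol),
    PE_P = minusWater(oracleAtoms(.glycerol, .enolEther(n1, d1),
                                  .fattyAcid(n2, d2), .phosphoric,
                                  .ethanolamine), 4),
    Cer = cer(),
    SM = minusWater(oracleAtoms(cer(), .phosphoric, .choline), 2),
    HexCer = minusWater(oracleAtoms(cer(), .hexose), 1),
    Sulf = oracleAtoms(minusWater(oracleAtoms(cer(), .hexose), 1),
                       c(S = 1, O = 3)),
    DG = minusWater(oracleAtoms(.glycerol, .fattyAcid(n1, d1),
                                .fattyAcid(n2, d2)), 2),
    stop("oracle does not model class ", class))
}

## ground-truth labeling helpers for planted-structure recovery
moduleTruthLabels <- function(study) {
  genes <- rownames(exprMatrix(study))
  lab <- rep(0L, length(genes))
  names(lab) <- genes
  tr <- metadata(study)$modules
  for (i in seq_along(tr)) lab[tr[[i]]] <- i
  lab
}

moduleCallLabels <- function(moduleSet, genes) {
  lab <- rep(0L, length(genes))
  names(lab) <- genes
  mods <- moduleGenes(moduleSet)
  for (i in seq_along(mods)) lab[mods[[i]]] <- i
  lab
}
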
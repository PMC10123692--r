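test_that("GPR strings parse into the expected expression trees", {
  tree <- parseGPR("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(unlist(tree$args[[1]]$args), c("g1", "g2"))
  expect_equal(tree$args[[2]], "g3")
  expect_null(parseGPR(""))
  expect_null(parseGPR(NA))
  expect_equal(parseGPR("g7"), "g7")
  # and binds tighter than or
  t2 <- parseGPR("g1 or g2 and g3")
  expect_equal(t2$op, "or")
  expect_error(parseGPR("g1 and (g2"), "GPR parse error")
  expect_error(parseGPR("g1 g2"), "GPR parse error")
})

test_that("GPR evaluation follows the min/max trinary rules", {
  expect_equal(evaluateGPR(parseGPR("g1 and g2"), c(g1 = 1, g2 = -1)), -1)
  expect_equal(evaluateGPR(parseGPR("g1 or g2"), c(g1 = -1, g2 = 0)), 0)
  expect_equal(evaluateGPR(NULL, c(g1 = 1)), 0)
  # missing genes count as moderate
  expect_equal(evaluateGPR(parseGPR("g1 and gX"), c(g1 = 1)), 0)
  # exhaustive 3-leaf truth table against an independent oracle
  tree <- parseGPR("(g1 and g2) or g3")
  grid <- expand.grid(g1 = -1:1, g2 = -1:1, g3 = -1:1)
  for (i in seq_len(nrow(grid))) {
    vals <- unlist(grid[i, ])
    expect_equal(evaluateGPR(tree, vals), oracle_gpr_eval(tree, vals))
  }
  expect_equal(evaluateGPR(tree, c(g1 = 1, g2 = -1, g3 = 0)), 0)
})

test_that("GPR evaluation is monotone in every gene", {
  set.seed(42)
  rand_tree <- function(genes) {
    if (length(genes) == 1) return(genes)
    split <- sample(seq_len(length(genes) - 1), 1)
    list(op = sample(c("and", "or"), 1),
         args = list(rand_tree(genes[1:split]),
                     rand_tree(genes[-(1:split)])))
  }
  for (rep in 1:20) {
    ng <- sample(2:4, 1)
    genes <- paste0("g", seq_len(ng))
    tree <- rand_tree(sample(genes))
    grid <- as.matrix(expand.grid(rep(list(-1:1), ng)))
    colnames(grid) <- genes
    for (i in seq_len(nrow(grid))) {
      v0 <- evaluateGPR(tree, grid[i, ])
      for (g in genes) {
        if (grid[i, g] < 1) {
          up <- grid[i, ]; up[g] <- up[g] + 1
          expect_gte(evaluateGPR(tree, up), v0)
        }
      }
    }
  }
})

test_that("stoichiometric matrix matches definition and brute-force assembly", {
  m <- chain3_model()
  S <- stoichiometricMatrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(as.numeric(S[, "R1"]), c(-1, 1))  # A -> B column
  toy <- generateToyGem(3, 4, 1, seed = 11)$model
  expect_equal(unname(as.matrix(stoichiometricMatrix(toy))),
               unname(oracle_stoich(toy)))
  expect_equal(ncol(stoichiometricMatrix(toy)), nrow(reactions(toy)))
  expect_equal(nrow(stoichiometricMatrix(toy)), nrow(metabolites(toy)))
})

test_that("model validity rejects broken constructions", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  expect_error(metabolicModel(S, lower_bound = 2, upper_bound = 1),
               "lower_bound")
  expect_error(
    metabolicModel(S, gpr = "g1", genes = character()),
    "absent from gene list")
  m <- metabolicModel(S)
  expect_s4_class(m, "MetabolicModel")
})

test_that("SBML round trip preserves ids, bounds, stoichiometry and GPRs", {
  toy <- generateToyGem(3, 4, 1, seed = 7)$model
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(toy, f)
  rt <- readSBML(f)
  expect_identical(reactionIds(rt), reactionIds(toy))
  expect_identical(metaboliteIds(rt), metaboliteIds(toy))
  expect_equal(fluxBounds(rt), fluxBounds(toy))
  expect_equal(as.matrix(stoichiometricMatrix(rt)),
               as.matrix(stoichiometricMatrix(toy)))
  expect_identical(reactions(rt)$gpr_string, reactions(toy)$gpr_string)
  expect_identical(reactions(rt)$subsystem, reactions(toy)$subsystem)
  expect_identical(reactions(rt)$kind, reactions(toy)$kind)
  expect_setequal(modelGenes(rt), modelGenes(toy))
})

test_that("readSBML handles legacy kinetic-law bounds and notes GPRs", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c"/>',
    '<species id="A_b" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (g1 and g2) or g3</p></body></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '<kineticLaw><math/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="99"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_b"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- readSBML(f)
  expect_equal(nrow(reactions(m)), 2L)
  expect_equal(nrow(metabolites(m)), 2L)  # boundary species dropped
  r1 <- reactions(m)[reactions(m)$id == "R1", ]
  expect_equal(r1$lower_bound, 0)
  expect_equal(r1$upper_bound, 99)
  expect_equal(r1$gpr_string, "(g1 and g2) or g3")
  expect_equal(as.numeric(stoichiometricMatrix(m)["B", "R1"]), 2)
  expect_equal(reactions(m)$kind[reactions(m)$id == "EX_A"], "exchange")
  expect_error(readSBML(withr::local_tempfile(lines = "not xml <")),
               "cannot parse")
})

test_that("a model written by the package is readable by cobrapy", {
  toy <- generateToyGem(3, 4, 1, seed = 7)$model
  f <- tempfile(fileext = ".xml")
  writeSBML(toy, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import warnings; warnings.filterwarnings('ignore');",
    "import cobra;",
    "m = cobra.io.read_sbml_model('", f, "');",
    "print(len(m.reactions), len(m.metabolites), len(m.genes))"
  ))), stdout = TRUE, stderr = FALSE)
  counts <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(counts, c(nrow(reactions(toy)), nrow(metabolites(toy)),
                         length(modelGenes(toy))))
})
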
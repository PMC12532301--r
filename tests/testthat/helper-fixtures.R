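# Shared fixtures, built once per test run. Everything is generated in
# code; no stored data.

fixGrid <- defaultGrid()
fixPre <- prereceptoralTemplate(fixGrid)
fixFund <- buildNormalFundamentals(fixGrid, pre = fixPre)
fixPenn <- makeInstrument("penn", grid = fixGrid)
fixOculus <- makeInstrument("oculus", grid = fixGrid)
fixNagel <- makeInstrument("nagel", grid = fixGrid)
fixNormal <- makeNormalObserver(fixFund)

anomObs <- function(kind, shift) makeAnomalousObserver(fixFund, kind, shift, fixPre)

# an instrument whose amber lies outside the red/green mixture gamut:
# no observer's reference ratio can be met by any mixture setting
offGamutPenn <- setAmberSpd(fixPenn, synthesizeLedSpd(700, 16, fixGrid))

argmaxWl <- function(spd) wavelengths(spd)[which.max(specValues(spd))]
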
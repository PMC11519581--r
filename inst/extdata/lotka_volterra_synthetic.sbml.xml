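<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic SBML Level 3 encoding of the packaged Lotka-Volterra fixture
     (hand-written test fixture, not exported from any external tool). -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="lotka_volterra_synthetic">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="prey" compartment="cell" initialConcentration="6"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="predator" compartment="cell" initialConcentration="2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="a" value="1.0" constant="true"/>
      <parameter id="b" value="0.4" constant="true"/>
      <parameter id="c" value="0.2" constant="true"/>
      <parameter id="delta" value="0.8" constant="true"/>
    </listOfParameters>
    <listOfRules>
      <rateRule variable="prey">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply>
            <minus/>
            <apply><times/><ci>a</ci><ci>prey</ci></apply>
            <apply><times/><ci>b</ci><ci>prey</ci><ci>predator</ci></apply>
          </apply>
        </math>
      </rateRule>
      <rateRule variable="predator">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply>
            <minus/>
            <apply><times/><ci>c</ci><ci>prey</ci><ci>predator</ci></apply>
            <apply><times/><ci>delta</ci><ci>predator</ci></apply>
          </apply>
        </math>
      </rateRule>
    </listOfRules>
  </model>
</sbml>
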
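<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_glycerol" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="GLC" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="TRI" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="GLY" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="ATP" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="ADP" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="O2" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="BIO" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_m1000" value="-1000" constant="true"/>
      <parameter id="ub_zero" value="0" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_zero">
        <listOfReactants>
          <speciesReference species="GLC" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="GLK" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="GLC" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="TRI" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="G2G" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="TRI" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="GLY" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="OXI" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="TRI" stoichiometry="1" constant="true"/>
          <speciesReference species="O2" stoichiometry="3" constant="true"/>
          <speciesReference species="ADP" stoichiometry="13.5" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ATP" stoichiometry="13.5" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOS" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="TRI" stoichiometry="1.5" constant="true"/>
          <speciesReference species="ATP" stoichiometry="10" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ADP" stoichiometry="10" constant="true"/>
          <speciesReference species="BIO" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_bio" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="BIO" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="NGAM" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="ATP" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ADP" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_o2" reversible="true" fast="false" fbc:lowerFluxBound="lb_m1000" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="O2" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_gly" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="GLY" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
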
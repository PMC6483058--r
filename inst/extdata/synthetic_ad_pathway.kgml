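<?xml version="1.0"?>
<!-- SYNTHETIC fixture: an Alzheimer-scale pathway map stand-in; gene symbols are real, the topology is engineered -->
<pathway name="path:synthetic_ad" org="hsa" number="99999" title="Synthetic AD-scale pathway">
    <entry id="1" name="APP" type="gene">
      <graphics name="APP" type="rectangle"/>
    </entry>
    <entry id="2" name="PSEN1" type="gene">
      <graphics name="PSEN1" type="rectangle"/>
    </entry>
    <entry id="3" name="PSEN2" type="gene">
      <graphics name="PSEN2" type="rectangle"/>
    </entry>
    <entry id="4" name="SNCA" type="gene">
      <graphics name="SNCA" type="rectangle"/>
    </entry>
    <entry id="5" name="CASP8" type="gene">
      <graphics name="CASP8" type="rectangle"/>
    </entry>
    <entry id="6" name="APAF1" type="gene">
      <graphics name="APAF1" type="rectangle"/>
    </entry>
    <entry id="7" name="CASP3" type="gene">
      <graphics name="CASP3" type="rectangle"/>
    </entry>
    <entry id="8" name="FLR01" type="gene">
      <graphics name="FLR01" type="rectangle"/>
    </entry>
    <entry id="9" name="FLR02" type="gene">
      <graphics name="FLR02" type="rectangle"/>
    </entry>
    <entry id="10" name="FLR03" type="gene">
      <graphics name="FLR03" type="rectangle"/>
    </entry>
    <entry id="11" name="FLR04" type="gene">
      <graphics name="FLR04" type="rectangle"/>
    </entry>
    <entry id="12" name="FLR05" type="gene">
      <graphics name="FLR05" type="rectangle"/>
    </entry>
    <entry id="13" name="FLR06" type="gene">
      <graphics name="FLR06" type="rectangle"/>
    </entry>
    <entry id="14" name="FLR07" type="gene">
      <graphics name="FLR07" type="rectangle"/>
    </entry>
    <entry id="15" name="FLR08" type="gene">
      <graphics name="FLR08" type="rectangle"/>
    </entry>
    <entry id="16" name="FLR09" type="gene">
      <graphics name="FLR09" type="rectangle"/>
    </entry>
    <entry id="17" name="FLR10" type="gene">
      <graphics name="FLR10" type="rectangle"/>
    </entry>
    <entry id="18" name="FLR11" type="gene">
      <graphics name="FLR11" type="rectangle"/>
    </entry>
    <entry id="19" name="FLR12" type="gene">
      <graphics name="FLR12" type="rectangle"/>
    </entry>
    <entry id="20" name="FLR13" type="gene">
      <graphics name="FLR13" type="rectangle"/>
    </entry>
    <entry id="21" name="FLR14" type="gene">
      <graphics name="FLR14" type="rectangle"/>
    </entry>
    <entry id="22" name="FLR15" type="gene">
      <graphics name="FLR15" type="rectangle"/>
    </entry>
    <entry id="23" name="FLR16" type="gene">
      <graphics name="FLR16" type="rectangle"/>
    </entry>
    <entry id="24" name="FLR17" type="gene">
      <graphics name="FLR17" type="rectangle"/>
    </entry>
    <entry id="25" name="FLR18" type="gene">
      <graphics name="FLR18" type="rectangle"/>
    </entry>
    <entry id="26" name="FLR19" type="gene">
      <graphics name="FLR19" type="rectangle"/>
    </entry>
    <entry id="27" name="FLR20" type="gene">
      <graphics name="FLR20" type="rectangle"/>
    </entry>
    <entry id="28" name="FLR21" type="gene">
      <graphics name="FLR21" type="rectangle"/>
    </entry>
    <entry id="29" name="FLR22" type="gene">
      <graphics name="FLR22" type="rectangle"/>
    </entry>
    <entry id="30" name="FLR23" type="gene">
      <graphics name="FLR23" type="rectangle"/>
    </entry>
    <entry id="31" name="FLR24" type="gene">
      <graphics name="FLR24" type="rectangle"/>
    </entry>
    <entry id="32" name="CAPN1" type="gene">
      <graphics name="CAPN1" type="rectangle"/>
    </entry>
    <entry id="33" name="APBB1" type="gene">
      <graphics name="APBB1" type="rectangle"/>
    </entry>
    <entry id="34" name="MAPT" type="gene">
      <graphics name="MAPT" type="rectangle"/>
    </entry>
    <entry id="200" name="cpd:C00027" type="compound"/>
    <entry id="201" name="path:hsa00000" type="map"/>
    <entry id="202" name="undefined" type="group"/>
    <relation entry1="1" entry2="2" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="1" entry2="3" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="1" entry2="4" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="1" entry2="5" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="1" entry2="6" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="2" entry2="7" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="3" entry2="7" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="4" entry2="7" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="5" entry2="7" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="6" entry2="7" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="8" entry2="9" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="10" entry2="11" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="12" entry2="13" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="14" entry2="15" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="16" entry2="17" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="18" entry2="19" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="20" entry2="21" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="21" entry2="22" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="23" entry2="24" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="24" entry2="25" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="26" entry2="27" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="27" entry2="28" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="29" entry2="30" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="30" entry2="31" type="PPrel">
      <subtype name="activation" value="--&gt;"/>
    </relation>
    <relation entry1="8" entry2="200" type="PCrel"/>
    <relation entry1="200" entry2="11" type="PCrel"/>
</pathway>
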
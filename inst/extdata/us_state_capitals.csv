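capital,state,lat,lon
Montgomery,AL,32.38,-86.30
Juneau,AK,58.30,-134.42
Phoenix,AZ,33.45,-112.07
Little Rock,AR,34.75,-92.29
Sacramento,CA,38.58,-121.49
Denver,CO,39.74,-104.98
Hartford,CT,41.76,-72.68
Dover,DE,39.16,-75.52
Tallahassee,FL,30.44,-84.28
Atlanta,GA,33.75,-84.39
Honolulu,HI,21.31,-157.86
Boise,ID,43.62,-116.20
Springfield,IL,39.80,-89.65
Indianapolis,IN,39.77,-86.16
Des Moines,IA,41.59,-93.60
Topeka,KS,39.05,-95.68
Frankfort,KY,38.19,-84.87
Baton Rouge,LA,30.46,-91.19
Augusta,ME,44.31,-69.78
Annapolis,MD,38.98,-76.49
Boston,MA,42.36,-71.06
Lansing,MI,42.73,-84.56
Saint Paul,MN,44.95,-93.09
Jackson,MS,32.30,-90.18
Jefferson City,MO,38.58,-92.17
Helena,MT,46.59,-112.04
Lincoln,NE,40.81,-96.70
Carson City,NV,39.16,-119.77
Concord,NH,43.21,-71.54
Trenton,NJ,40.22,-74.76
Santa Fe,NM,35.69,-105.94
Albany,NY,42.65,-73.76
Raleigh,NC,35.78,-78.64
Bismarck,ND,46.81,-100.78
Columbus,OH,39.96,-83.00
Oklahoma City,OK,35.47,-97.52
Salem,OR,44.94,-123.03
Harrisburg,PA,40.26,-76.88
Providence,RI,41.82,-71.41
Columbia,SC,34.00,-81.03
Pierre,SD,44.37,-100.35
Nashville,TN,36.16,-86.78
Austin,TX,30.27,-97.74
Salt Lake City,UT,40.76,-111.89
Montpelier,VT,44.26,-72.58
Richmond,VA,37.54,-77.44
Olympia,WA,47.04,-122.90
Charleston,WV,38.35,-81.63
Madison,WI,43.07,-89.40
Cheyenne,WY,41.14,-104.82
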
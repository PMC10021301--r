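# One Indian city per line; used for city extraction from site/EC free text.
# Editable: add rows as needed. Lines starting with '#' are ignored.
Mumbai
Navi Mumbai
Delhi
New Delhi
Bengaluru
Bangalore
Chennai
Kolkata
Hyderabad
Secunderabad
Pune
Ahmedabad
Jaipur
Lucknow
Kanpur
Nagpur
Indore
Bhopal
Patna
Vadodara
Surat
Ludhiana
Agra
Varanasi
Madurai
Coimbatore
Kochi
Thiruvananthapuram
Trivandrum
Mysuru
Mysore
Mangaluru
Mangalore
Hubli
Hubballi
Belgaum
Guwahati
Bhubaneswar
Cuttack
Ranchi
Raipur
Chandigarh
Amritsar
Jodhpur
Udaipur
Gwalior
Jabalpur
Aurangabad
Nashik
Solapur
Kolhapur
Vijayawada
Visakhapatnam
Guntur
Warangal
Tirupati
Salem
Tiruchirappalli
Vellore
Puducherry
Pondicherry
Noida
Ghaziabad
Faridabad
Gurugram
Meerut
Bareilly
Allahabad
Prayagraj
Dehradun
Shimla
Srinagar
Jammu
Manipal
Karad
Wardha
Sevagram
Thane
Howrah
Dhanbad
Jamshedpur
Rohtak
Hisar
Bikaner
Kota
Ajmer
Rajkot
Bhavnagar
Jamnagar
Anand
Nellore
Kakinada
Davangere
Shivamogga
Kozhikode
Thrissur
Kottayam
Alappuzha
Imphal
Agartala
Shillong
Aligarh
Gorakhpur
Jhansi
Rishikesh
Haridwar
Ambala
Patiala
Sangli
Akola
Amravati
Latur
Nanded
Berhampur
Sambalpur
Kalaburagi
Gulbarga
Bijapur
Bidar
Tumkur
Udupi
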